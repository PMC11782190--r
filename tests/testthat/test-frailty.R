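test_that("MET expenditure follows the IPAQ linear combination", {
  expect_equal(met_expenditure(30, 7, 0, 0, 0, 0), 693)
  expect_equal(met_expenditure(0, 0, 0, 0, 0, 0), 0)
  expect_equal(met_expenditure(10, 2, 20, 3, 5, 1), 346)
  expect_error(met_expenditure(-1, 2, 0, 0, 0, 0), "non-negative")
  expect_error(met_expenditure(10, 8, 0, 0, 0, 0), "exceed 7")
})

test_that("sex-stratified quantile flags the extreme fifth per stratum", {
  vals <- 1:10
  sex <- rep("F", 10)
  low <- sex_stratified_quantile_cut(vals, sex, "lowest")
  expect_identical(which(low), 1:2)
  # all equal: everyone flagged (degenerate convention)
  eq <- sex_stratified_quantile_cut(rep(5, 8), rep("M", 8), "lowest")
  expect_true(all(eq))
  expect_error(sex_stratified_quantile_cut(1:3, rep("F", 3), "lowest"),
               "fewer than")
  # mixed-sex data vs an independent per-stratum quantile oracle
  set.seed(71)
  v <- rnorm(60); s <- sample(c("F", "M"), 60, replace = TRUE)
  hi <- sex_stratified_quantile_cut(v, s, "highest")
  oracle <- logical(60)
  for (g in c("F", "M"))
    oracle[s == g] <- v[s == g] >= quantile(v[s == g], 0.8)
  expect_identical(as.logical(hi), oracle)
})

test_that("dichotomization applies the clinical thresholds", {
  p <- data.frame(
    participant_id = c("a", "b", "c"),
    sex = c("F", "F", "M"),
    tug_s = c(14.0, 13.5, 10),
    moca = c(26, 25, 30),
    gait_ms = c(0.6, 0.61, 1.0),
    fr_cm = c(14.9, 15, 30),
    adl_score = c(5, 6, 7),
    weight_loss = c(TRUE, FALSE, FALSE),
    exhaustion = c(TRUE, FALSE, FALSE),
    fall = c(FALSE, TRUE, FALSE))
  ind <- frailty_indicators(p)
  expect_identical(ind$slow_tug, c(TRUE, FALSE, FALSE))       # strict > 13.5
  expect_identical(ind$cognition_impaired, c(FALSE, TRUE, FALSE))  # strict < 26
  expect_identical(ind$slow_gait, c(TRUE, FALSE, FALSE))      # <= 0.6
  expect_identical(ind$balance_impaired, c(TRUE, FALSE, FALSE))    # strict < 15
  expect_identical(ind$adl_compromised, c(TRUE, FALSE, FALSE))     # <= 5
  # missing quantile inputs give NA indicators, not errors
  expect_true(all(is.na(ind$weak_grip)))
})

test_that("the Fried count composes its five criteria and is monotone", {
  base <- data.frame(sex = rep("F", 6),
                     weight_loss = FALSE, met_score = c(10, 20, 30, 40, 50, 60),
                     sitting_hours = c(60, 50, 40, 30, 20, 10),
                     tug_s = 10, hgs_kg = c(10, 20, 30, 40, 50, 60),
                     exhaustion = FALSE)
  ind <- frailty_indicators(base)
  expect_true(all(ind$fried_count >= 0 & ind$fried_count <= 5, na.rm = TRUE))
  expect_equal(ind$fried_count,
               ind$weight_loss + (ind$low_activity | ind$sedentary) +
                 ind$slow_tug + ind$weak_grip + ind$exhaustion)
  # switching an indicator on never decreases the count
  worse <- base; worse$weight_loss <- TRUE; worse$tug_s <- 20
  ind2 <- frailty_indicators(worse)
  expect_true(all(ind2$fried_count >= ind$fried_count))
  expect_identical(ind2$fried_positive, ind2$fried_count >= 2)
})

test_that("2x2 odds ratios obey the symmetry invariants", {
  expect_equal(odds_ratio_2x2(10, 20, 10, 20)$or, 1)
  a <- odds_ratio_2x2(30, 80, 20, 90)
  # swapping exposure groups inverts the OR
  b <- odds_ratio_2x2(20, 90, 30, 80)
  expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
  expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-12)
  # swapping outcome labels in both groups inverts the OR too
  c_ <- odds_ratio_2x2(50, 80, 70, 90)
  expect_equal(a$or, 1 / c_$or, tolerance = 1e-12)
  expect_true(a$ci_low <= a$or && a$or <= a$ci_high)
  expect_error(odds_ratio_2x2(0, 20, 10, 20), "zero cell")
  expect_s3_class(odds_ratio_2x2(0, 20, 10, 20, continuity = TRUE), "association")
})

test_that("logistic fit with only the group term reproduces the 2x2 OR", {
  set.seed(81)
  exposed <- rep(c(TRUE, FALSE), c(120, 150))
  outcome <- c(rbinom(120, 1, 0.35), rbinom(150, 1, 0.2))
  tab <- odds_ratio_2x2(sum(outcome[exposed]), 120, sum(outcome[!exposed]), 150)
  fit <- fit_logistic(outcome, exposed)
  expect_equal(fit$or, tab$or, tolerance = 1e-6)
  expect_equal(fit$ci_low, tab$ci_low, tolerance = 1e-6)
  expect_equal(fit$ci_high, tab$ci_high, tolerance = 1e-6)
  expect_equal(fit$p, tab$p, tolerance = 1e-5)
})

test_that("IRLS optimum dominates a brute-force likelihood grid", {
  set.seed(82)
  n <- 30
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x + 0.5 * z))
  fit <- fit_logistic(y, x == 1, data.frame(z = z))
  loglik <- function(b) {
    eta <- b[1] + b[2] * x + b[3] * z
    sum(y * eta - log1p(exp(eta)))
  }
  grid <- expand.grid(b0 = seq(-3, 3, 0.25), b1 = seq(-3, 3, 0.25),
                      b2 = seq(-3, 3, 0.25))
  best_grid <- max(apply(grid, 1, loglik))
  co <- coef(fit$fit)
  expect_gte(loglik(c(co[1], co[grep("exposed", names(co))], co["z"])) + 1e-9,
             best_grid)
})

test_that("Wald intervals achieve near-nominal coverage at true OR 2", {
  set.seed(83)
  hits <- 0L
  for (r in 1:200) {
    x <- rbinom(2000, 1, 0.5)
    y <- rbinom(2000, 1, plogis(-1 + log(2) * x))
    f <- fit_logistic(y, x == 1)
    if (f$ci_low <= 2 && 2 <= f$ci_high) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.90)
  expect_lt(hits / 200, 0.995)
})

test_that("cluster associations cover every indicator x cluster x model cell", {
  sim <- simulate_cohort(n = 600, seed = 6)
  p <- sim$participants
  p$final_group <- p$true_group
  res <- cluster_associations(p, c("slow_gait", "fried_positive"))
  expect_equal(nrow(res), 2 * 3 * 3)
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high, na.rm = TRUE))
  expect_true(all(res$or > 0, na.rm = TRUE))
})

test_that("group comparisons match a textbook chi-squared computation", {
  counts <- rbind(A = c(20, 30), B = c(35, 15), C = c(25, 25))
  df <- data.frame(
    final_group = rep(rownames(counts), times = rowSums(counts)),
    flag = unlist(lapply(1:3, function(i)
      rep(c(TRUE, FALSE), counts[i, ]))))
  res <- compare_groups(df, c(flag = "categorical"))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  expect_equal(res$overall$statistic, stat, tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)

  # identical groups: overall p near 1
  df2 <- data.frame(final_group = rep(c("A", "B"), each = 100),
                    flag = rep(c(TRUE, FALSE), 100))
  res2 <- compare_groups(df2, c(flag = "categorical"))
  expect_gt(res2$overall$p, 0.9)
})

test_that("Bonferroni-significant implies significant at 0.05", {
  set.seed(85)
  df <- data.frame(final_group = rep(c("A", "B", "C"), each = 50),
                   v = c(rnorm(50), rnorm(50, 1), rnorm(50, 0.3)))
  res <- compare_groups(df, c(v = "continuous"))
  expect_true(all(res$pairwise$p[res$pairwise$significant] < 0.05))
})
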