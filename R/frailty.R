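#' Weekly metabolic-equivalent (MET) expenditure
#'
#' `3.3 * walking min/day * walking days/week + 4.0 * moderate min/day *
#' moderate days/week + 8.0 * vigorous min/day * vigorous days/week`, the
#' IPAQ scoring used to grade physical activity.
#'
#' @param walk_min,mod_min,vig_min minutes per day of walking / moderate /
#'   vigorous activity (non-negative).
#' @param walk_days,mod_days,vig_days days per week (0-7).
#' @return MET score (vectorized).
#' @export
met_expenditure <- function(walk_min, walk_days, mod_min, mod_days,
                            vig_min, vig_days) {
  args <- list(walk_min, walk_days, mod_min, mod_days, vig_min, vig_days)
  if (any(vapply(args, function(a) any(a < 0, na.rm = TRUE), logical(1))))
    stop("activity inputs must be non-negative")
  if (any(c(walk_days, mod_days, vig_days) > 7, na.rm = TRUE))
    stop("days per week cannot exceed 7")
  3.3 * walk_min * walk_days + 4.0 * mod_min * mod_days + 8.0 * vig_min * vig_days
}

#' Sex-stratified quantile flags
#'
#' Computes the empirical `fraction` quantile of `values` within each sex
#' stratum and flags membership in the extreme fifth: `values <= cutoff` for
#' `side = "lowest"`, `values >= cutoff` for `side = "highest"`. When all
#' values in a stratum are equal, every member is flagged (degenerate case).
#'
#' @param values numeric vector (NA allowed, propagated).
#' @param sexes factor/character vector of strata, same length.
#' @param side `"lowest"` or `"highest"`.
#' @param fraction quantile fraction, default 0.2 (quintile).
#' @param min_stratum minimum non-missing values per stratum (default 5).
#' @return logical vector of flags; per-stratum cutoffs in attribute
#'   `"cutoffs"`.
#' @export
sex_stratified_quantile_cut <- function(values, sexes, side = c("lowest", "highest"),
                                        fraction = 0.2, min_stratum = 5L) {
  side <- match.arg(side)
  stopifnot(length(values) == length(sexes), fraction > 0, fraction < 1)
  out <- rep(NA, length(values))
  cutoffs <- c()
  for (s in unique(as.character(sexes))) {
    in_s <- as.character(sexes) == s
    v <- values[in_s]
    if (sum(!is.na(v)) < min_stratum)
      stop("stratum '", s, "' has fewer than ", min_stratum, " values")
    p <- if (side == "lowest") fraction else 1 - fraction
    cut <- stats::quantile(v, p, na.rm = TRUE, names = FALSE)
    out[in_s] <- if (side == "lowest") v <= cut else v >= cut
    cutoffs[s] <- cut
  }
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Analysis configuration: dichotomization thresholds
#'
#' Clinical cutpoints used by [frailty_indicators()], with the Bonferroni
#' level used for post hoc pairwise comparisons.
#'
#' @param tug_slow_s timed up-and-go threshold (s), slow if greater.
#' @param moca_cut MoCA score, impaired if strictly below.
#' @param gait_slow_ms gait speed (m/s), slow if at or below.
#' @param fr_cut_cm functional reach (cm), impaired if strictly below.
#' @param adl_cut Katz ADL score, compromised if at or below.
#' @param quantile_fraction fraction for the sex-stratified extreme-fifth
#'   rules (grip strength, MET, sitting time), default 0.2.
#' @param bonferroni_alpha significance level for pairwise comparisons,
#'   default 0.017.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(tug_slow_s = 13.5, moca_cut = 26, gait_slow_ms = 0.6,
                            fr_cut_cm = 15, adl_cut = 5, quantile_fraction = 0.2,
                            bonferroni_alpha = 0.017) {
  stopifnot(tug_slow_s > 0, moca_cut > 0, gait_slow_ms > 0, fr_cut_cm > 0,
            adl_cut > 0, quantile_fraction > 0, quantile_fraction < 1,
            bonferroni_alpha > 0)
  structure(as.list(environment()), class = "analysis_config")
}

#' Dichotomize raw assessments into frailty indicators
#'
#' Applies the clinical thresholds of [analysis_config()] and the
#' sex-stratified extreme-fifth rules to a cohort table of raw assessment
#' values, and composes the Fried phenotype count. Missing raw values give
#' `NA` indicators (complete-case handling downstream). Expected columns
#' (any may be absent, the dependent indicators are then `NA`): `sex`,
#' `weight_loss` (logical), `met_score`, `sitting_hours`, `tug_s`, `hgs_kg`,
#' `exhaustion` (logical), `adl_score`, `moca`, `gait_ms`, `fr_cm`, `fall`
#' (logical).
#'
#' @param participants data frame of raw cohort values, one row per
#'   participant, with a `sex` column for the stratified rules.
#' @param cfg an [analysis_config()].
#' @return data frame of logical indicator columns `weight_loss`,
#'   `low_activity`, `sedentary`, `slow_tug`, `weak_grip`, `exhaustion`,
#'   `adl_compromised`, `cognition_impaired`, `slow_gait`,
#'   `balance_impaired`, `recent_fall`, plus `fried_count` (0-5) and
#'   `fried_positive` (count >= 2).
#' @export
frailty_indicators <- function(participants, cfg = analysis_config()) {
  p <- participants
  n <- nrow(p)
  col <- function(name) if (name %in% names(p)) p[[name]] else rep(NA, n)
  strat <- function(values, side) {
    if (all(is.na(values))) return(rep(NA, n))
    as.logical(sex_stratified_quantile_cut(values, p$sex, side,
                                           fraction = cfg$quantile_fraction))
  }
  out <- data.frame(
    weight_loss = as.logical(col("weight_loss")),
    low_activity = strat(col("met_score"), "lowest"),
    sedentary = strat(col("sitting_hours"), "highest"),
    slow_tug = col("tug_s") > cfg$tug_slow_s,
    weak_grip = strat(col("hgs_kg"), "lowest"),
    exhaustion = as.logical(col("exhaustion")),
    adl_compromised = col("adl_score") <= cfg$adl_cut,
    cognition_impaired = col("moca") < cfg$moca_cut,
    slow_gait = col("gait_ms") <= cfg$gait_slow_ms,
    balance_impaired = col("fr_cm") < cfg$fr_cut_cm,
    recent_fall = as.logical(col("fall")))
  out$fried_count <- out$weight_loss + (out$low_activity | out$sedentary) +
    out$slow_tug + out$weak_grip + out$exhaustion
  out$fried_positive <- out$fried_count >= 2
  if ("participant_id" %in% names(p))
    out <- cbind(participant_id = p$participant_id, out)
  out
}

wald_z <- 1.959964

#' Unadjusted odds ratio from a 2x2 table
#'
#' Cross-product odds ratio of an indicator in an exposed group versus a
#' reference group, with the Wald 95% confidence interval
#' `exp(log(OR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` and the Wald p-value
#' from `z = log(OR) / SE`.
#'
#' @param cases_exposed,n_exposed positive count and size of the exposed
#'   group.
#' @param cases_ref,n_ref positive count and size of the reference group.
#' @param continuity add 0.5 to every cell (only needed when a cell is 0;
#'   default `FALSE`, zero cells are an error).
#' @return list of class `association`: `or`, `ci_low`, `ci_high`, `p`,
#'   `log_or`, `se`.
#' @export
odds_ratio_2x2 <- function(cases_exposed, n_exposed, cases_ref, n_ref,
                           continuity = FALSE) {
  a <- cases_exposed; b <- n_exposed - cases_exposed
  c_ <- cases_ref;    d <- n_ref - cases_ref
  if (any(c(a, b, c_, d) < 0)) stop("counts imply a negative cell")
  if (any(c(a, b, c_, d) == 0)) {
    if (!continuity) stop("zero cell in 2x2 table (set continuity = TRUE to correct)")
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  log_or <- log(a * d / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  structure(list(or = exp(log_or),
                 ci_low = exp(log_or - wald_z * se),
                 ci_high = exp(log_or + wald_z * se),
                 p = 2 * stats::pnorm(-abs(log_or / se)),
                 log_or = log_or, se = se),
            class = "association")
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f, %.2f), Wald p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Logistic odds ratio for one cluster term
#'
#' Fits a binomial logistic regression (maximum likelihood via the IRLS
#' algorithm of [stats::glm()]) of a binary outcome on a cluster-membership
#' indicator plus covariates, and returns the Wald odds ratio, 95% CI and
#' p-value for the cluster term. With no covariates this reproduces
#' [odds_ratio_2x2()] exactly.
#'
#' @param outcome logical/0-1 outcome vector.
#' @param exposed logical cluster-membership indicator (reference group
#'   `FALSE`).
#' @param covariates optional data frame of adjustment covariates.
#' @return list of class `association` (see [odds_ratio_2x2()]), with the
#'   fitted `glm` in `$fit`.
#' @export
fit_logistic <- function(outcome, exposed, covariates = NULL) {
  df <- data.frame(.y = as.integer(outcome), .exposed = as.logical(exposed))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  if (!fit$converged) stop("logistic regression did not converge")
  sm <- summary(fit)$coefficients
  term <- grep("^\\.exposed", rownames(sm), value = TRUE)
  if (length(term) != 1L) stop("cluster term missing from fit")
  est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
  if (se > 50) stop("separation suspected for term ", term)
  structure(list(or = exp(est), ci_low = exp(est - wald_z * se),
                 ci_high = exp(est + wald_z * se),
                 p = 2 * stats::pnorm(-abs(est / se)),
                 log_or = est, se = se, fit = fit),
            class = "association")
}

#' Cluster-versus-NOR association table
#'
#' For every frailty indicator and every morphology cluster, estimates the
#' odds ratio against the NOR reference group under three logistic models:
#' unadjusted; adjusted for age and sex; and fully adjusted (age, sex, BMI,
#' resting SBP, cardiovascular disease, diabetes, antihypertensive use,
#' polypharmacy, elevated hsCRP — those present in `data`). Complete-case
#' per indicator.
#'
#' @param data data frame with a `final_group` column (morphologies plus
#'   `"NOR"`), the indicator columns, and any covariate columns.
#' @param indicators character vector of indicator column names.
#' @param models subset of `c("unadjusted", "age_sex", "full")`.
#' @param full_covariates covariate columns for the fully adjusted model.
#' @param ref reference group label, default `"NOR"`.
#' @return data frame with one row per indicator x cluster x model:
#'   `indicator`, `cluster`, `model`, `or`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
cluster_associations <- function(data, indicators,
                                 models = c("unadjusted", "age_sex", "full"),
                                 full_covariates = c("age", "sex", "bmi",
                                                     "resting_sbp", "cvd",
                                                     "diabetes", "antihypertensives",
                                                     "polypharmacy", "crp_high"),
                                 ref = "NOR") {
  stopifnot("final_group" %in% names(data), ref %in% data$final_group)
  models <- match.arg(models, several.ok = TRUE)
  clusters <- setdiff(unique(data$final_group), ref)
  cov_sets <- list(
    unadjusted = character(0),
    age_sex = intersect(c("age", "sex"), names(data)),
    full = intersect(full_covariates, names(data)))
  rows <- list()
  for (ind in indicators) {
    for (cl in clusters) {
      sub <- data[data$final_group %in% c(cl, ref), , drop = FALSE]
      for (m in models) {
        covs <- cov_sets[[m]]
        # near-separation in sparse cells raises glm warnings; the SE guard
        # in fit_logistic converts true separation into an NA row
        res <- tryCatch(
          suppressWarnings(
            fit_logistic(sub[[ind]], sub$final_group == cl,
                         if (length(covs)) sub[, covs, drop = FALSE] else NULL)),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          indicator = ind, cluster = cl, model = m,
          or = if (is.null(res)) NA_real_ else res$or,
          ci_low = if (is.null(res)) NA_real_ else res$ci_low,
          ci_high = if (is.null(res)) NA_real_ else res$ci_high,
          p = if (is.null(res)) NA_real_ else res$p,
          n = sum(stats::complete.cases(sub[, c(ind, covs), drop = FALSE])),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Descriptive comparison of final groups
#'
#' Per variable: an overall test across groups (chi-squared for categorical,
#' Kruskal-Wallis or one-way ANOVA for continuous) and post hoc pairwise
#' comparisons (chi-squared for categorical, Welch t-tests for continuous)
#' with a Bonferroni significance flag.
#'
#' @param data data frame with a `final_group` column and the variables.
#' @param variables named character vector: names are column names, values
#'   are `"categorical"`, `"continuous"` (Kruskal-Wallis) or `"anova"`.
#' @param alpha Bonferroni-corrected pairwise significance level, default
#'   0.017.
#' @return list with `overall` (variable, test, statistic, p) and
#'   `pairwise` (variable, pair, difference, p, significant) data frames.
#' @export
compare_groups <- function(data, variables, alpha = 0.017) {
  stopifnot("final_group" %in% names(data))
  g <- factor(data$final_group)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) == 0L)) stop("empty group")
  overall <- list(); pairwise <- list()
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  for (v in names(variables)) {
    x <- data[[v]]
    type <- variables[[v]]
    if (type == "categorical") {
      tt <- stats::chisq.test(table(g, x))
      overall[[v]] <- data.frame(variable = v, test = "chi-squared",
                                 statistic = unname(tt$statistic), p = tt$p.value)
    } else if (type == "anova") {
      tt <- summary(stats::aov(x ~ g))[[1L]]
      overall[[v]] <- data.frame(variable = v, test = "anova",
                                 statistic = tt$`F value`[1L], p = tt$`Pr(>F)`[1L])
    } else {
      tt <- stats::kruskal.test(x, g)
      overall[[v]] <- data.frame(variable = v, test = "kruskal-wallis",
                                 statistic = unname(tt$statistic), p = tt$p.value)
    }
    for (pr in pairs) {
      xi <- x[g == pr[1L]]; xj <- x[g == pr[2L]]
      if (type == "categorical") {
        ct <- stats::chisq.test(rbind(c(sum(xi, na.rm = TRUE), sum(!is.na(xi)) - sum(xi, na.rm = TRUE)),
                                      c(sum(xj, na.rm = TRUE), sum(!is.na(xj)) - sum(xj, na.rm = TRUE))))
        diff <- mean(xi, na.rm = TRUE) - mean(xj, na.rm = TRUE)
        p <- ct$p.value
      } else {
        tt2 <- stats::t.test(xi, xj)
        diff <- mean(xi, na.rm = TRUE) - mean(xj, na.rm = TRUE)
        p <- tt2$p.value
      }
      pairwise[[paste(v, pr[1L], pr[2L])]] <- data.frame(
        variable = v, pair = paste(pr, collapse = " vs "),
        difference = diff, p = p, significant = p < alpha)
    }
  }
  list(overall = do.call(rbind, c(overall, make.row.names = FALSE)),
       pairwise = do.call(rbind, c(pairwise, make.row.names = FALSE)))
}
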