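test_that("k-means++ seeding follows the D-squared law on three points", {
  x <- matrix(c(0, 0, 1, 0, 5, 0), ncol = 2, byrow = TRUE)
  set.seed(123)
  draws <- replicate(10000, attr(kmeanspp_init(x, 2), "idx"))
  first <- draws[1, ]
  # first centre uniform over the points
  expect_true(all(abs(tabulate(first, 3) / 10000 - 1 / 3) <
                    3 * sqrt((1 / 3) * (2 / 3) / 10000)))
  # second centre proportional to squared distance from the first
  d2 <- as.matrix(dist(x))^2
  for (i in 1:3) {
    sel <- draws[2, first == i]
    n_i <- length(sel)
    probs <- d2[i, ] / sum(d2[i, ])
    for (j in setdiff(1:3, i)) {
      se <- sqrt(probs[j] * (1 - probs[j]) / n_i)
      expect_lt(abs(mean(sel == j) - probs[j]), 3 * se)
    }
  }
})

test_that("seeding edge cases: k = n permutation, duplicated point, k > n", {
  x <- matrix(rnorm(12), ncol = 3)
  init <- kmeanspp_init(x, 4, seed = 1)
  expect_setequal(attr(init, "idx"), 1:4)
  dup <- matrix(rep(c(2, 3), each = 6), ncol = 2)
  expect_equal(unname(kmeanspp_init(dup, 1, seed = 1)[1, ]), c(2, 3))
  expect_error(kmeanspp_init(x, 5), "1 <= k")
})

test_that("well-separated groups are recovered exactly and fits are deterministic", {
  set.seed(77)
  x <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
             matrix(rnorm(40, 50, 0.1), ncol = 2))
  fit <- fit_kmeans(x, 2, seed = 5)
  expect_equal(length(unique(fit$cluster[1:20])), 1L)
  expect_equal(length(unique(fit$cluster[21:40])), 1L)
  expect_true(fit$cluster[1] != fit$cluster[40])
  refit <- fit_kmeans(x, 2, seed = 5)
  expect_identical(fit$cluster, refit$cluster)
  expect_identical(fit$i_conv, refit$i_conv)
})

test_that("Lloyd inertia is non-increasing across iterations", {
  set.seed(19)
  for (rep in 1:10) {
    x <- matrix(rnorm(60), ncol = 3)
    fit <- fit_kmeans(x, 3, n_init = 3, seed = NULL)
    expect_true(all(diff(fit$inertia_trace) <= 1e-10))
  }
})

test_that("silhouette matches a hand-computed 4-point case and conventions", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(1, 1, 2, 2)
  # a = 1 for all points; b = 10.5 / 9.5 for outer/inner points
  expect_equal(silhouette_score(x, labels), ((10.5 - 1) / 10.5 + (9.5 - 1) / 9.5) / 2)
  # identical points in two arbitrary groups score 0 by the a = b = 0 rule
  same <- matrix(1, nrow = 6, ncol = 2)
  expect_equal(silhouette_score(same, rep(1:2, 3)), 0)
  expect_error(silhouette_score(x, rep(1, 4)), "two clusters")
  # separation limit: tight distant clusters approach 1
  far <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
               matrix(rnorm(20, 1000, 0.01), ncol = 2))
  expect_gt(silhouette_score(far, rep(1:2, each = 10)), 0.999)
})

test_that("silhouette separates split Gaussians better than merged ones", {
  set.seed(101)
  x <- rbind(matrix(rnorm(100, 0, 1), ncol = 2), matrix(rnorm(100, 8, 1), ncol = 2))
  good <- silhouette_score(x, rep(1:2, each = 50))
  merged <- silhouette_score(x, sample(rep(1:2, 50)))
  expect_gt(good, merged)
})

test_that("bootstrap Jaccard is 1 for perfectly separated clusters", {
  set.seed(55)
  x <- rbind(matrix(rnorm(30, 0, 0.1), ncol = 2),
             matrix(rnorm(30, 100, 0.1), ncol = 2))
  expect_equal(bootstrap_jaccard(x, 2, B = 20, n_init = 3, seed = 1), 1)
})

test_that("bootstrap Jaccard is low on structureless uniform data", {
  set.seed(56)
  x <- matrix(runif(200), ncol = 2)
  j <- bootstrap_jaccard(x, 2, B = 50, n_init = 3, seed = 2)
  expect_lt(j, 0.9)
  expect_gt(j, 0)
})

test_that("cluster quality geometry: two-point cluster and per-point oracle", {
  x <- matrix(c(0, 0, 4, 0, 100, 0, 104, 0), ncol = 2, byrow = TRUE)
  fit <- fit_kmeans(x, 2, seed = 1)
  q <- cluster_quality(x, fit, B = 0)
  expect_equal(sort(q$d_c), c(2, 2))       # centroid at the midpoint
  expect_equal(sort(q$diameter), c(2, 2))
  expect_equal(q$d_cc[1, 2], 100)
  expect_equal(q$d_cc, t(q$d_cc))
  expect_equal(diag(q$d_cc), c(`1` = 0, `2` = 0))

  set.seed(21)
  y <- matrix(rnorm(30), ncol = 3)
  fy <- fit_kmeans(y, 2, seed = 3)
  qy <- cluster_quality(y, fy, B = 0)
  for (j in 1:2) {
    pts <- y[fy$cluster == j, , drop = FALSE]
    dd <- sqrt(rowSums((pts - matrix(fy$centers[j, ], nrow(pts), 3, byrow = TRUE))^2))
    expect_equal(qy$d_c[j], mean(dd))
    expect_equal(qy$diameter[j], max(dd))
    expect_lte(qy$d_c[j], qy$diameter[j])
    expect_equal(qy$d_c_per_feature[j, ],
                 colMeans(abs(sweep(pts, 2, fy$centers[j, ]))))
  }
})

test_that("centroid distances from the observed-cohort centroids match the reported set", {
  centres <- rbind(iOHYPO = c(-15.2, 0.7, 0.3),
                   OHYPO = c(-35.6, -15.5, -13.4),
                   OHYPER = c(2.2, 17.3, 15.6))
  d <- sort(as.numeric(dist(centres)))
  expect_true(all(abs(d - sort(c(28.56, 29.50, 57.95))) < 0.2))
})

test_that("morphology labelling ranks by the stabilization coordinate", {
  fit <- list(k = 3L,
              centers = rbind(c(-15.2, 0.7, 0.3), c(-35.6, -15.5, -13.4),
                              c(2.2, 17.3, 15.6)))
  expect_equal(label_morphologies(fit), c("iOHYPO", "OHYPO", "OHYPER"))
  fit$centers <- rbind(c(0, 5, 0), c(0, -5, 0), c(0, 0, 0))
  expect_equal(label_morphologies(fit), c("OHYPER", "OHYPO", "iOHYPO"))
  fit$centers <- rbind(c(0, 5, 0), c(0, 5, 1), c(0, 0, 0))
  expect_error(label_morphologies(fit), "ambiguous")
})
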