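# squared Euclidean distances between rows of x (n x d) and rows of c (k x d)
sqdist <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' k-means++ seeding (D-squared law)
#'
#' The first centre is drawn uniformly from the points; each subsequent
#' centre is drawn with probability proportional to its squared Euclidean
#' distance to the nearest centre already chosen.
#'
#' @param x numeric matrix (points in rows).
#' @param k number of centres, `1 <= k <= nrow(x)`.
#' @param seed optional integer seed (uses and restores the global RNG
#'   stream when `NULL`).
#' @return `k x ncol(x)` matrix of initial centres, with the chosen row
#'   indices in attribute `"idx"`.
#' @export
kmeanspp_init <- function(x, k, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("need 1 <= k <= number of points")
  with_seed(seed, {
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    if (k > 1L) {
      d2 <- sqdist(x, x[idx[1L], , drop = FALSE])[, 1L]
      for (j in 2:k) {
        if (sum(d2) <= 0) {
          # all remaining points coincide with a chosen centre
          idx[j] <- sample.int(n, 1L)
        } else {
          idx[j] <- sample.int(n, 1L, prob = d2)
        }
        d2 <- pmin(d2, sqdist(x, x[idx[j], , drop = FALSE])[, 1L])
      }
    }
    structure(x[idx, , drop = FALSE], idx = idx)
  })
}

lloyd <- function(x, centers, max_iter, tol) {
  n <- nrow(x); k <- nrow(centers)
  inertia_trace <- numeric(0)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters to the point farthest from its assigned centre
    nearest <- d2[cbind(seq_len(n), labels)]
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        far <- which.max(nearest)
        centers[j, ] <- x[far, ]
        labels[far] <- j
        d2 <- sqdist(x, centers)
        labels <- max.col(-d2, ties.method = "first")
        nearest <- d2[cbind(seq_len(n), labels)]
      }
    }
    inertia_trace <- c(inertia_trace, sum(nearest))
    new_centers <- centers
    for (j in seq_len(k))
      new_centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- sqdist(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(centers = centers, labels = labels, inertia = inertia,
       i_conv = it, inertia_trace = inertia_trace)
}

#' Fit k-means with k-means++ seeding and restarts
#'
#' Lloyd iterations from [kmeanspp_init()] starts, keeping the best of
#' `n_init` runs by within-cluster sum of squared distances (inertia).
#' Iterations stop when the largest centroid shift falls below `tol` or
#' after `max_iter` iterations; an emptied cluster is re-seeded to the point
#' farthest from its current centre. The per-iteration inertia trace is
#' retained and is non-increasing (Lloyd monotonicity).
#'
#' @inheritParams kmeanspp_init
#' @param n_init number of random restarts (default 10).
#' @param max_iter maximum Lloyd iterations per restart (default 300).
#' @param tol convergence tolerance on centroid shift (default 1e-6).
#' @param seed integer seed (default 0) for reproducible restarts; `NULL`
#'   uses the current RNG stream.
#' @return object of class `ortho_kmeans`: `k`, `centers`, `cluster`
#'   (1-based labels), `inertia`, `i_conv` (iterations of the winning run),
#'   `inertia_trace`.
#' @export
fit_kmeans <- function(x, k, n_init = 10, max_iter = 300, tol = 1e-6, seed = 0) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("points must have finite coordinates")
  if (k < 1 || k > nrow(x)) stop("need 1 <= k <= number of points")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      init <- kmeanspp_init(x, k)
      attr(init, "idx") <- NULL
      fit <- lloyd(x, init, max_iter, tol)
      if (any(diff(fit$inertia_trace) > 1e-8 * max(1, fit$inertia_trace[1L])))
        stop("internal error: inertia increased during Lloyd iterations")
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    structure(list(k = k, centers = best$centers, cluster = best$labels,
                   inertia = best$inertia, i_conv = best$i_conv,
                   inertia_trace = best$inertia_trace),
              class = "ortho_kmeans")
  })
}

#' @export
print.ortho_kmeans <- function(x, ...) {
  cat(sprintf("<ortho_kmeans> k = %d, n = %d, inertia = %.4g, converged in %d iterations\n",
              x$k, length(x$cluster), x$inertia, x$i_conv))
  cat("centres:\n")
  print(round(x$centers, 3))
  invisible(x)
}

#' Mean silhouette score
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to another cluster; the
#' silhouette is `(b - a) / max(a, b)`. Singleton-cluster points and points
#' with `max(a, b) = 0` contribute 0.
#'
#' @param x numeric matrix of points.
#' @param labels integer cluster labels (at least two non-empty clusters).
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette requires at least two clusters")
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster
  md <- sapply(seq_len(k), function(j) rowSums(d[, labels == j, drop = FALSE]) / sizes[j])
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- md[i, ci] * sizes[ci] / (sizes[ci] - 1L)  # exclude self
    b <- min(md[i, -ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard cluster stability
#'
#' Refits the clustering on `B` bootstrap resamples. For each reference
#' cluster the maximum Jaccard overlap with any bootstrap cluster is taken,
#' restricted to the points shared by the original data and the resample;
#' the statistic is the average over clusters and resamples. A degenerate
#' resample with fewer distinct points than `k` is redrawn.
#'
#' @inheritParams fit_kmeans
#' @param B number of bootstrap resamples (default 100).
#' @param ref optional pre-fitted reference `ortho_kmeans` on `x`.
#' @return mean Jaccard coefficient in `[0, 1]`.
#' @export
bootstrap_jaccard <- function(x, k, B = 100, n_init = 10, max_iter = 300,
                              tol = 1e-6, seed = 0, ref = NULL) {
  stopifnot(B >= 1)
  x <- as.matrix(x)
  n <- nrow(x)
  with_seed(seed, {
    if (is.null(ref)) ref <- fit_kmeans(x, k, n_init, max_iter, tol, seed = NULL)
    ref_sets <- split(seq_len(n), ref$cluster)
    js <- numeric(B)
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (nrow(unique(x[idx, , drop = FALSE])) >= k) break
      }
      fit <- fit_kmeans(x[idx, , drop = FALSE], k, n_init, max_iter, tol, seed = NULL)
      shared <- unique(idx)
      boot_sets <- lapply(split(idx, fit$cluster), unique)
      per_cluster <- vapply(ref_sets, function(rs) {
        rs <- intersect(rs, shared)
        max(vapply(boot_sets, function(bs) jaccard(rs, bs), numeric(1)))
      }, numeric(1))
      js[b] <- mean(per_cluster)
    }
    mean(js)
  })
}

#' Cluster quality metrics
#'
#' Euclidean geometry in the Delta% feature space: per-cluster mean distance
#' to centre (`d_c`), maximum distance to centre (`diameter`), pairwise
#' centroid distance matrix (`d_cc`), per-axis mean absolute deviation from
#' the centre (`d_c_per_feature`), mean silhouette, and optionally the
#' bootstrap Jaccard stability.
#'
#' @param x numeric matrix of points used for the fit.
#' @param model an `ortho_kmeans` fit on `x`.
#' @param B bootstrap resamples for the Jaccard coefficient; `0` skips it.
#' @param seed seed for the bootstrap.
#' @return list of class `cluster_quality`.
#' @export
cluster_quality <- function(x, model, B = 100, seed = 0) {
  x <- as.matrix(x)
  k <- model$k
  d <- sqrt(sqdist(x, model$centers))
  own <- d[cbind(seq_len(nrow(x)), model$cluster)]
  d_c <- vapply(seq_len(k), function(j) mean(own[model$cluster == j]), numeric(1))
  diameter <- vapply(seq_len(k), function(j) max(own[model$cluster == j]), numeric(1))
  d_cc <- as.matrix(stats::dist(model$centers))
  dimnames(d_cc) <- list(seq_len(k), seq_len(k))
  d_c_feat <- t(vapply(seq_len(k), function(j) {
    colMeans(abs(sweep(x[model$cluster == j, , drop = FALSE], 2, model$centers[j, ])))
  }, numeric(ncol(x))))
  sil <- if (k >= 2L) silhouette_score(x, model$cluster) else NA_real_
  jac <- if (B > 0) bootstrap_jaccard(x, k, B = B, seed = seed) else NA_real_
  structure(list(d_c = d_c, diameter = diameter, d_cc = d_cc,
                 d_c_per_feature = d_c_feat, silhouette = sil, jaccard = jac,
                 i_conv = model$i_conv),
            class = "cluster_quality")
}

#' @export
print.cluster_quality <- function(x, ...) {
  k <- length(x$d_c)
  tab <- data.frame(cluster = seq_len(k), d_c = round(x$d_c, 2),
                    diameter = round(x$diameter, 2),
                    round(x$d_c_per_feature, 2))
  print(tab, row.names = FALSE)
  cat("centroid distances (d_cc):\n")
  print(round(x$d_cc, 2))
  cat(sprintf("silhouette %.3f, bootstrap Jaccard %s, %d iterations to convergence\n",
              x$silhouette,
              if (is.na(x$jaccard)) "not computed" else sprintf("%.3f", x$jaccard),
              x$i_conv))
  invisible(x)
}

#' Map k = 3 clusters to orthostatic morphologies
#'
#' Ranks centroids on the stabilization-point coordinate: the highest is the
#' persistent-rise morphology (OHYPER, akin to orthostatic hypertension),
#' the lowest the sustained-deficit morphology (OHYPO, akin to classic
#' orthostatic hypotension) and the middle one the initial-deficit
#' morphology (iOHYPO, akin to initial orthostatic hypotension).
#'
#' @param model an `ortho_kmeans` fit with `k = 3` on the feature matrix
#'   (columns early, stabilization, late Delta%).
#' @return character vector of length 3, morphology name per cluster index.
#' @export
label_morphologies <- function(model) {
  if (model$k != 3L) stop("morphology labelling is defined for k = 3")
  stab <- model$centers[, 2L]
  if (anyDuplicated(stab))
    stop("ambiguous morphology: tied stabilization-point coordinates")
  lab <- character(3)
  lab[which.max(stab)] <- "OHYPER"
  lab[which.min(stab)] <- "OHYPO"
  lab[lab == ""] <- "iOHYPO"
  lab
}
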