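#' Fit the postural blood-pressure morphology model
#'
#' The core analysis: clusters participants' three-feature Delta% SBP
#' vectors (early phase, stabilization point, late phase) with k-means++
#' (own implementation, restarts, Lloyd iterations), labels the k = 3
#' clusters as orthostatic morphologies by their stabilization-point
#' coordinate, computes cluster-quality diagnostics, and reassigns
#' participants with a normal orthostatic response (NOR) — SBP change within
#' 20% of baseline in the early phase and within 10% at the stabilization
#' point and late phase — out of their clusters into the NOR reference
#' group.
#'
#' Features are clustered unstandardized: all three are commensurate Delta%
#' units. Set `standardize = TRUE` to z-score them first.
#'
#' @param features data frame with columns `participant_id`, `early_pct`,
#'   `stab_pct`, `late_pct` (e.g. from [extract_features_cohort()] or
#'   [simulate_cohort()]).
#' @param k number of clusters (default 3; morphology labels and NOR
#'   reassignment require 3).
#' @param nor_limits NOR bounds in percentage points, default
#'   `c(20, 10, 10)`.
#' @param standardize z-score features before clustering (default `FALSE`).
#' @param n_init,max_iter,tol,seed see [fit_kmeans()].
#' @param bootstrap_B bootstrap resamples for the Jaccard stability metric
#'   (default 100; 0 skips it).
#' @return object of class `bp_morphology`: the k-means fit (`$kmeans`),
#'   `$morphology` (label per cluster index), `$quality`
#'   ([cluster_quality()]), `$groups` and `$reassignment` (NOR step, k = 3
#'   only), plus the input features.
#' @seealso [predict.bp_morphology()], [summary.bp_morphology()]
#' @examples
#' cohort <- simulate_cohort(n = 300, seed = 1)
#' fit <- bp_morphology(cohort$participants, bootstrap_B = 10)
#' fit
#' table(fitted(fit))
#' @export
bp_morphology <- function(features, k = 3, nor_limits = c(20, 10, 10),
                          standardize = FALSE, n_init = 10, max_iter = 300,
                          tol = 1e-6, seed = 0, bootstrap_B = 100) {
  if (!"participant_id" %in% names(features))
    features$participant_id <- sprintf("P%04d", seq_len(nrow(features)))
  x <- feature_matrix(features)
  xs <- if (standardize) scale(x) else x
  km <- fit_kmeans(xs, k, n_init = n_init, max_iter = max_iter, tol = tol,
                   seed = seed)
  if (standardize) {
    centers <- sweep(sweep(km$centers, 2, attr(xs, "scaled:scale"), "*"),
                     2, attr(xs, "scaled:center"), "+")
  } else centers <- km$centers
  quality <- cluster_quality(xs, km, B = bootstrap_B, seed = seed)
  morph <- if (k == 3L) {
    m <- km; m$centers <- centers
    label_morphologies(m)
  } else paste0("cluster", seq_len(k))
  assignments <- data.frame(participant_id = features$participant_id,
                            cluster = morph[km$cluster],
                            stringsAsFactors = FALSE)
  reass <- if (k == 3L) reassign_groups(assignments, features, nor_limits) else
    list(groups = cbind(assignments,
                        original_cluster = assignments$cluster,
                        final_group = assignments$cluster)[,
                        c("participant_id", "original_cluster", "final_group")],
         summary = NULL)
  structure(list(kmeans = km, centers = centers, morphology = morph,
                 quality = quality, groups = reass$groups,
                 reassignment = reass$summary, features = features,
                 nor_limits = nor_limits, standardize = standardize,
                 seed = seed),
            class = "bp_morphology")
}

#' @export
print.bp_morphology <- function(x, ...) {
  cat(sprintf("Postural blood-pressure morphology model (k = %d, n = %d)\n",
              x$kmeans$k, nrow(x$features)))
  cat("centroids (Delta%% SBP: early, stabilization, late):\n")
  ctr <- round(x$centers, 2)
  rownames(ctr) <- x$morphology
  colnames(ctr) <- c("early", "stab", "late")
  print(ctr)
  cat("final groups:\n")
  print(table(x$groups$final_group))
  invisible(x)
}

#' @export
summary.bp_morphology <- function(object, ...) {
  structure(list(fit = object), class = "summary.bp_morphology")
}

#' @export
print.summary.bp_morphology <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\ninertia %.2f; %d iterations to convergence\n",
              f$kmeans$inertia, f$kmeans$i_conv))
  print(f$quality)
  if (!is.null(f$reassignment)) {
    cat("NOR reassignment:\n")
    print(f$reassignment, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.bp_morphology <- function(object, ...) {
  ctr <- object$centers
  rownames(ctr) <- object$morphology
  colnames(ctr) <- c("early_pct", "stab_pct", "late_pct")
  ctr
}

#' @export
fitted.bp_morphology <- function(object, ...) {
  stats::setNames(factor(object$groups$final_group),
                  object$groups$participant_id)
}

#' Assign new feature vectors to morphology groups
#'
#' Nearest-centroid assignment in the (optionally standardized) feature
#' space, followed by the NOR reassignment rule.
#'
#' @param object a [bp_morphology] fit.
#' @param newdata data frame with `early_pct`, `stab_pct`, `late_pct`.
#' @param ... unused.
#' @return character vector of final group labels.
#' @export
predict.bp_morphology <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  ctr <- object$centers
  lab <- object$morphology[max.col(-sqdist(x, ctr), ties.method = "first")]
  if (object$kmeans$k == 3L)
    lab[classify_nor(newdata, object$nor_limits)] <- "NOR"
  lab
}

#' Pairs plot of the clustered feature space
#'
#' @param x a [bp_morphology] fit.
#' @param ... passed to [graphics::pairs()].
#' @export
plot.bp_morphology <- function(x, ...) {
  m <- feature_matrix(x$features)
  colnames(m) <- c("early Delta%", "stab Delta%", "late Delta%")
  grp <- factor(x$groups$final_group)
  graphics::pairs(m, col = as.integer(grp), pch = 20,
                  main = "Postural SBP morphology clusters", ...)
  invisible(x)
}

#' Residual feature distances to the assigned centroid
#'
#' @param object a [bp_morphology] fit.
#' @param ... unused.
#' @return matrix of per-feature differences between each participant's
#'   features and their assigned cluster centroid (Delta% units).
#' @export
residuals.bp_morphology <- function(object, ...) {
  x <- feature_matrix(object$features)
  x - object$centers[object$kmeans$cluster, , drop = FALSE]
}
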