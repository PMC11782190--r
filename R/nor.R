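#' Normal orthostatic response (NOR) predicate
#'
#' A participant has a normal orthostatic response when the SBP change from
#' baseline stays within 20 percentage points in the early phase and within
#' 10 percentage points at both the stabilization point and the late phase
#' (inclusive bounds). The wider early margin accommodates the higher blood
#' pressure variability of the first 15 s of standing.
#'
#' @param features data frame with columns `early_pct`, `stab_pct`,
#'   `late_pct` (Delta% from baseline).
#' @param limits positive bounds `c(early, stab, late)` in percentage
#'   points, default `c(20, 10, 10)`.
#' @return logical vector, one element per row of `features`.
#' @export
classify_nor <- function(features, limits = c(20, 10, 10)) {
  stopifnot(length(limits) == 3L, all(limits > 0))
  m <- feature_matrix(features)
  if (!all(is.finite(m))) stop("features must be finite")
  abs(m[, 1L]) <= limits[1L] & abs(m[, 2L]) <= limits[2L] & abs(m[, 3L]) <= limits[3L]
}

#' Reassign NOR participants out of their clusters
#'
#' Applies the NOR predicate to every participant; those satisfying it are
#' moved from their original morphology cluster into the NOR reference
#' group, all others keep their cluster.
#'
#' @param assignments data frame with columns `participant_id` and `cluster`
#'   (morphology label per participant).
#' @param features feature data frame with `participant_id` and the three
#'   Delta% columns, same participants.
#' @param limits see [classify_nor()].
#' @return list with `groups` (data frame `participant_id`,
#'   `original_cluster`, `final_group`) and `summary` (data frame per
#'   cluster: `original_n`, `final_n`, `reduction_pct` rounded to 1 dp, plus
#'   a NOR row).
#' @export
reassign_groups <- function(assignments, features, limits = c(20, 10, 10)) {
  stopifnot(is.data.frame(assignments),
            all(c("participant_id", "cluster") %in% names(assignments)))
  if (!setequal(assignments$participant_id, features$participant_id) ||
      nrow(assignments) != nrow(features))
    stop("assignments and features must cover the same participants")
  features <- features[match(assignments$participant_id, features$participant_id), ]
  is_nor <- classify_nor(features, limits)
  groups <- data.frame(
    participant_id = assignments$participant_id,
    original_cluster = as.character(assignments$cluster),
    final_group = ifelse(is_nor, "NOR", as.character(assignments$cluster)),
    stringsAsFactors = FALSE)
  cl <- sort(unique(groups$original_cluster))
  orig <- vapply(cl, function(g) sum(groups$original_cluster == g), integer(1))
  fin <- vapply(cl, function(g) sum(groups$final_group == g), integer(1))
  summary <- data.frame(
    group = c(cl, "NOR"),
    original_n = c(orig, 0L),
    final_n = c(fin, sum(is_nor)),
    reduction_pct = c(round(100 * (orig - fin) / orig, 1), NA_real_),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(groups = groups, summary = summary)
}
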