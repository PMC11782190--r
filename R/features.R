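#' Mean over a half-open window of a uniform series
#'
#' @param series a `bp_series` on the 1-s grid.
#' @param span numeric length-2 `[a, b)` window in seconds.
#' @return mean of the grid values in the span (mmHg).
#' @export
windowed_mean <- function(series, span) {
  stopifnot(length(span) == 2L, span[1] < span[2])
  mean(series_window(series, span[1L], span[2L]))
}

delta_pair <- function(value, baseline) {
  c(pct = 100 * (value - baseline) / baseline, mmhg = value - baseline)
}

#' Early-phase SBP change: nadir of trailing 2-s means in the first 15 s
#'
#' The nadir point is the minimum over trailing `avg`-second means whose
#' windows lie fully inside `(0, window_end]`; with the 1-s grid and
#' `avg = 2` these are the means of grid pairs \{t-1, t\} for
#' t = 2, ..., 15. The earliest window wins ties.
#'
#' @param series a `bp_series` covering `(0, window_end]`.
#' @param baseline baseline SBP (mmHg).
#' @param window_end end of the search window (s), default 15.
#' @param avg smoothing width (s), default 2.
#' @return named vector `c(pct, mmhg)`: percentage and absolute change from
#'   baseline (drops negative).
#' @export
early_phase_delta <- function(series, baseline, window_end = 15, avg = 2) {
  ends <- seq(avg, window_end)
  means <- vapply(ends, function(e) mean(series_window(series, e - avg + 1, e + 1)),
                  numeric(1))
  delta_pair(means[which.min(means)], baseline)
}

#' Stabilization-point SBP change: 5-s mean centred on 40 s
#'
#' Mean of the grid values over `[center - w, center + w]` with
#' `w = floor(width/2)` (for the defaults, grid points 38..42), expressed as
#' change from baseline.
#'
#' @inheritParams early_phase_delta
#' @param center centre of the window (s), default 40.
#' @param width window width (s, odd), default 5.
#' @return named vector `c(pct, mmhg)`.
#' @export
stabilization_delta <- function(series, baseline, center = 40, width = 5) {
  stopifnot(width %% 2 == 1)
  w <- (width - 1) / 2
  delta_pair(mean(series_window(series, center - w, center + w + 1)), baseline)
}

#' Late-phase SBP change: nadir period of 10-s rolling means in 60-120 s
#'
#' Computes the rolling mean over every window `[s, s + width)` with integer
#' start s = `window[1]`, ..., `window[2] - width`, all lying inside the late
#' window, and takes the minimum (earliest window on ties).
#'
#' @inheritParams early_phase_delta
#' @param window search window, default `c(60, 120)`.
#' @param width rolling-window width (s), default 10.
#' @return named vector `c(pct, mmhg)`.
#' @export
late_phase_delta <- function(series, baseline, window = c(60, 120), width = 10) {
  starts <- seq(window[1L], window[2L] - width)
  means <- vapply(starts, function(s) mean(series_window(series, s, s + width)),
                  numeric(1))
  delta_pair(means[which.min(means)], baseline)
}

#' Extract the clustering feature vector from one recording
#'
#' Interpolates the SBP series to the uniform 1-s grid over the baseline and
#' standing windows, computes the supine baseline, and derives the three
#' morphology features (early phase, stabilization point, late phase) as
#' percentage and absolute change from baseline.
#'
#' @param rec a [bp_recording] covering `[-60, 120]` s.
#' @return one-row data frame: `participant_id`, `baseline`, `early_pct`,
#'   `stab_pct`, `late_pct`, `early_mmhg`, `stab_mmhg`, `late_mmhg`.
#' @export
extract_features <- function(rec) {
  series <- interpolate_uniform(rec, c(-60, 121))
  baseline <- compute_baseline(series)
  e <- early_phase_delta(series, baseline)
  s <- stabilization_delta(series, baseline)
  l <- late_phase_delta(series, baseline)
  data.frame(participant_id = attr(rec, "participant_id"),
             baseline = baseline,
             early_pct = unname(e["pct"]), stab_pct = unname(s["pct"]),
             late_pct = unname(l["pct"]),
             early_mmhg = unname(e["mmhg"]), stab_mmhg = unname(s["mmhg"]),
             late_mmhg = unname(l["mmhg"]),
             stringsAsFactors = FALSE)
}

#' Extract features for a list of recordings
#'
#' @param recs list of [bp_recording] objects.
#' @return data frame, one row per recording (see [extract_features()]).
#' @export
extract_features_cohort <- function(recs) {
  do.call(rbind, lapply(recs, extract_features))
}

# pull the 3-column Delta% matrix out of a feature data frame
feature_matrix <- function(features) {
  need <- c("early_pct", "stab_pct", "late_pct")
  if (!all(need %in% names(features)))
    stop("feature table must contain columns ", paste(need, collapse = ", "))
  as.matrix(features[, need])
}
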