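#' Beat-to-beat active-stand recordings
#'
#' A `bp_recording` holds one participant's beat-indexed systolic/diastolic
#' blood pressure and inter-beat (RR) interval series from an active stand
#' test. Time is in seconds relative to stand onset (`t = 0`); negative times
#' are supine. Each row is one heartbeat; `rr` is the inter-beat interval
#' ending at that beat, in seconds.
#'
#' @param t numeric vector of beat times (s relative to stand onset),
#'   strictly increasing.
#' @param sbp,dbp numeric vectors, systolic/diastolic pressure (mmHg),
#'   `sbp > dbp > 0` beat-wise.
#' @param rr numeric vector of inter-beat intervals (s), all positive.
#' @param participant_id single character id.
#' @return An object of class `bp_recording`: a data frame with columns
#'   `t`, `sbp`, `dbp`, `rr` and attributes `participant_id`, `supine_span`
#'   (seconds of data before stand onset) and `stand_span` (seconds after).
#' @export
bp_recording <- function(t, sbp, dbp, rr, participant_id = "P000") {
  n <- length(t)
  if (n == 0L) stop("recording must contain at least one beat")
  if (length(sbp) != n || length(dbp) != n || length(rr) != n)
    stop("t, sbp, dbp, rr must have equal length")
  if (anyNA(t) || anyNA(sbp) || anyNA(dbp) || anyNA(rr))
    stop("recording contains missing values")
  if (any(diff(t) <= 0))
    stop("beat times must be strictly increasing")
  if (any(dbp <= 0) || any(sbp <= dbp))
    stop("pressure invariant violated: need sbp > dbp > 0 for every beat")
  if (any(rr <= 0)) stop("rr intervals must be positive")
  out <- data.frame(t = as.numeric(t), sbp = as.numeric(sbp),
                    dbp = as.numeric(dbp), rr = as.numeric(rr))
  attr(out, "participant_id") <- as.character(participant_id)
  attr(out, "supine_span") <- max(0, -out$t[1L])
  attr(out, "stand_span") <- max(0, out$t[n])
  class(out) <- c("bp_recording", "data.frame")
  out
}

#' @export
print.bp_recording <- function(x, ...) {
  cat(sprintf("<bp_recording> %s: %d beats, supine %.1f s, stand %.1f s\n",
              attr(x, "participant_id"), nrow(x),
              attr(x, "supine_span"), attr(x, "stand_span")))
  invisible(x)
}

#' Read a beat-to-beat recording from delimited text
#'
#' One file per participant. Lines starting with `#` are header metadata of
#' the form `# key=value`; `stand_onset` (default 0) gives the stand-onset
#' time on the file's own clock, subtracted so that `t = 0` is stand onset in
#' the returned recording. Data columns are `t_sec,sbp_mmhg,dbp_mmhg,rr_sec`.
#'
#' @param path file path.
#' @param sep field separator (default `","`; use `"\t"` for TSV).
#' @return A [bp_recording].
#' @export
read_bp_recording <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list(stand_onset = 0, participant_id = sub("\\.[^.]*$", "", basename(path)))
  for (h in hdr) {
    kv <- sub("^\\s*#\\s*", "", h)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      meta[[key]] <- val
    }
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("no data rows in ", path)
  con <- textConnection(body)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, header = TRUE, sep = sep, stringsAsFactors = FALSE),
    error = function(e) stop("malformed table in ", path, ": ", conditionMessage(e))
  )
  need <- c("t_sec", "sbp_mmhg", "dbp_mmhg", "rr_sec")
  if (!all(need %in% names(df)))
    stop("missing columns in ", path, ": ", paste(setdiff(need, names(df)), collapse = ", "))
  for (cc in need) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("parse error in %s: non-numeric %s at data line %d", path, cc, bad[1L]))
    df[[cc]] <- v
  }
  onset <- as.numeric(meta$stand_onset)
  if (!is.finite(onset)) stop("invalid stand_onset header in ", path)
  bp_recording(df$t_sec - onset, df$sbp_mmhg, df$dbp_mmhg, df$rr_sec,
               participant_id = meta$participant_id)
}

#' Write a recording in the package's text dialect
#'
#' @param rec a [bp_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bp_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bp_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# participant_id=%s", attr(rec, "participant_id")),
               "# stand_onset=0",
               "t_sec,sbp_mmhg,dbp_mmhg,rr_sec"), con)
  writeLines(sprintf("%.10g,%.10g,%.10g,%.10g", rec$t, rec$sbp, rec$dbp, rec$rr), con)
  invisible(path)
}

#' Quality-control configuration
#'
#' Threshold set for [screen_quality()]. The screening rules are this
#' package's own operational stand-in for signal vetting (flatline, spike,
#' gap, supine calibration step, phase coverage); they are not a published
#' clinical standard.
#'
#' @param flatline_sd SBP standard deviation (mmHg) below which a span is a
#'   flatline.
#' @param flatline_span minimum flat span length (s).
#' @param spike_mmhg single-beat SBP excursion (mmHg) vs both neighbours.
#' @param gap_sec maximum tolerated inter-beat gap (s).
#' @param step_mmhg supine-phase shift between adjacent 10-s means (mmHg)
#'   flagged as a calibration step.
#' @param min_supine,min_stand minimum phase coverage (s).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(flatline_sd = 0.1, flatline_span = 10, spike_mmhg = 40,
                      gap_sec = 3, step_mmhg = 30, min_supine = 60,
                      min_stand = 120) {
  stopifnot(flatline_sd > 0, flatline_span > 0, spike_mmhg > 0, gap_sec > 0,
            step_mmhg > 0, min_supine > 0, min_stand > 0)
  structure(list(flatline_sd = flatline_sd, flatline_span = flatline_span,
                 spike_mmhg = spike_mmhg, gap_sec = gap_sec,
                 step_mmhg = step_mmhg, min_supine = min_supine,
                 min_stand = min_stand),
            class = "qc_config")
}

#' Screen a recording for signal-quality anomalies
#'
#' Deterministic rule-based screening. Flags raised:
#' * `short_phase` — supine coverage < `min_supine` s or standing coverage
#'   < `min_stand` s;
#' * `flatline` — SBP standard deviation below `flatline_sd` over any span of
#'   at least `flatline_span` s (cuff lock-up / lost pulse);
#' * `spike` — a single beat deviating more than `spike_mmhg` from both
#'   neighbours with reversion (the neighbours agree within `spike_mmhg`);
#' * `gap` — an inter-beat interval longer than `gap_sec` s;
#' * `calibration_step` — during the supine phase (t < -5 s), a jump larger
#'   than `step_mmhg` between adjacent 10-s window means (brachial
#'   recalibration artefact).
#'
#' @param rec a [bp_recording].
#' @param cfg a [qc_config].
#' @return list of class `qc_report` with elements `passed` (logical),
#'   `flags` (character vector) and `spans` (named list of flagged time
#'   spans/indices).
#' @export
screen_quality <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "bp_recording"))
  flags <- character(0)
  spans <- list()
  t <- rec$t; sbp <- rec$sbp; n <- nrow(rec)

  if (attr(rec, "supine_span") < cfg$min_supine ||
      attr(rec, "stand_span") < cfg$min_stand) {
    flags <- c(flags, "short_phase")
    spans$short_phase <- c(supine = attr(rec, "supine_span"),
                           stand = attr(rec, "stand_span"))
  }

  # flatline: SD of the beats within any flatline_span-second window
  if (n >= 3L) {
    j <- findInterval(t + cfg$flatline_span, t)
    for (i in seq_len(n)) {
      if (t[i] + cfg$flatline_span > t[n]) break  # window past the recording
      if (j[i] >= i + 2L && stats::sd(sbp[i:j[i]]) < cfg$flatline_sd) {
        flags <- c(flags, "flatline")
        spans$flatline <- c(t[i], t[j[i]])
        break
      }
    }
  }

  if (n >= 3L) {
    mid <- 2:(n - 1L)
    d_prev <- sbp[mid] - sbp[mid - 1L]
    d_next <- sbp[mid] - sbp[mid + 1L]
    revert <- abs(sbp[mid + 1L] - sbp[mid - 1L]) <= cfg$spike_mmhg
    hit <- which(abs(d_prev) > cfg$spike_mmhg & abs(d_next) > cfg$spike_mmhg &
                   sign(d_prev) == sign(d_next) & revert)
    if (length(hit)) {
      flags <- c(flags, "spike")
      spans$spike <- t[mid[hit]]
    }
  }

  gaps <- which(diff(t) > cfg$gap_sec)
  if (length(gaps)) {
    flags <- c(flags, "gap")
    spans$gap <- cbind(from = t[gaps], to = t[gaps + 1L])
  }

  sup <- which(t < -5)
  if (length(sup) > 4L) {
    edges <- seq(floor(min(t[sup])), -5, by = 10)
    if (length(edges) >= 3L) {
      bin <- cut(t[sup], edges, right = FALSE)
      m <- tapply(sbp[sup], bin, mean)
      m <- m[!is.na(m)]
      if (length(m) >= 2L && any(abs(diff(m)) > cfg$step_mmhg)) {
        flags <- c(flags, "calibration_step")
        spans$calibration_step <- unname(which(abs(diff(m)) > cfg$step_mmhg))
      }
    }
  }

  structure(list(passed = length(flags) == 0L, flags = unique(flags),
                 spans = spans, participant_id = attr(rec, "participant_id")),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s%s\n", x$participant_id,
              if (x$passed) "passed" else "FAILED",
              if (x$passed) "" else paste0(" [", paste(x$flags, collapse = ", "), "]")))
  invisible(x)
}

#' Interpolate a recording onto a uniform 1-s grid
#'
#' Linear interpolation of the per-beat SBP series at integer seconds inside
#' the half-open window `[window[1], window[2])`. No extrapolation: every
#' grid point must lie between the first and last beat.
#'
#' @param rec a [bp_recording].
#' @param window numeric length-2, window `[a, b)` in seconds relative to
#'   stand onset.
#' @param field which beat series to interpolate (default `"sbp"`).
#' @return list of class `bp_series` with integer-second `t` and `values`.
#' @export
interpolate_uniform <- function(rec, window, field = "sbp") {
  stopifnot(inherits(rec, "bp_recording"), length(window) == 2L,
            window[1] < window[2])
  grid <- seq(ceiling(window[1]), ceiling(window[2]) - 1L)
  if (grid[1L] < rec$t[1L] || grid[length(grid)] > rec$t[nrow(rec)])
    stop(sprintf("coverage error: beats span [%.1f, %.1f] but window needs [%d, %d]",
                 rec$t[1L], rec$t[nrow(rec)], grid[1L], grid[length(grid)]))
  v <- stats::approx(rec$t, rec[[field]], xout = grid, method = "linear")$y
  structure(list(t = grid, values = v, field = field,
                 participant_id = attr(rec, "participant_id")),
            class = "bp_series")
}

#' @export
print.bp_series <- function(x, ...) {
  cat(sprintf("<bp_series> %s %s: %d points, t in [%d, %d] s\n",
              x$participant_id, x$field, length(x$t), x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

# values of a bp_series on the half-open grid window [a, b); coverage-checked
series_window <- function(series, a, b) {
  idx <- which(series$t >= a & series$t < b)
  want <- seq(ceiling(a), ceiling(b) - 1L)
  if (length(idx) != length(want))
    stop(sprintf("coverage error: series does not cover [%s, %s)", a, b))
  series$values[idx]
}

#' Supine baseline SBP
#'
#' Arithmetic mean of the uniform 1-s SBP grid over `[-60, -30)` s, i.e.
#' 60-30 s before stand onset. This window precedes anticipatory pressure
#' rises while avoiding motion noise at the transition.
#'
#' @param series a `bp_series` from [interpolate_uniform()] covering
#'   `[-60, -30)`.
#' @param window baseline window, default `c(-60, -30)`.
#' @return baseline SBP in mmHg.
#' @export
compute_baseline <- function(series, window = c(-60, -30)) {
  mean(series_window(series, window[1L], window[2L]))
}

#' Resting cardiovascular indices from the supine baseline
#'
#' SBP and DBP are baseline-window (`[-60, -30)` s) means of the respective
#' interpolated series; pulse pressure `pp = sbp - dbp`; mean arterial
#' pressure `map = (sbp + 2 dbp) / 3`; heart rate `hr = 60 / mean(rr)` over
#' beats in the window; the RR 30:15 ratio divides the RR interval of the
#' beat nearest 30 s after standing by that of the beat nearest 15 s (heart
#' rate recovery marker).
#'
#' @param rec a [bp_recording] covering the baseline window and the first
#'   30 s of standing.
#' @param window baseline window, default `c(-60, -30)`.
#' @return list of class `resting_indices`: `sbp`, `dbp`, `pp`, `map`, `hr`,
#'   `rr_30_15`.
#' @export
resting_indices <- function(rec, window = c(-60, -30)) {
  s_sbp <- interpolate_uniform(rec, window, "sbp")
  s_dbp <- interpolate_uniform(rec, window, "dbp")
  sbp <- mean(s_sbp$values)
  dbp <- mean(s_dbp$values)
  in_win <- rec$t >= window[1L] & rec$t < window[2L]
  if (!any(in_win)) stop("coverage error: no beats in baseline window")
  hr <- 60 / mean(rec$rr[in_win])
  if (max(rec$t) < 30) stop("coverage error: no beats near t = 30 s")
  rr15 <- rec$rr[which.min(abs(rec$t - 15))]
  rr30 <- rec$rr[which.min(abs(rec$t - 30))]
  structure(list(sbp = sbp, dbp = dbp, pp = sbp - dbp,
                 map = (sbp + 2 * dbp) / 3, hr = hr, rr_30_15 = rr30 / rr15),
            class = "resting_indices")
}

#' @export
print.resting_indices <- function(x, ...) {
  cat(sprintf("SBP %.1f  DBP %.1f  PP %.1f  MAP %.1f mmHg  HR %.1f bpm  RR30:15 %.2f\n",
              x$sbp, x$dbp, x$pp, x$map, x$hr, x$rr_30_15))
  invisible(x)
}
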