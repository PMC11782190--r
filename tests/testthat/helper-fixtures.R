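# fixtures built in code: uniform series, plain recordings, deterministic
# archetypes

series_of <- function(t, values) {
  structure(list(t = as.integer(t), values = as.numeric(values),
                 field = "sbp", participant_id = "fixture"),
            class = "bp_series")
}

# recording with beats at given times following value vectors (recycled)
beats_recording <- function(t, sbp, dbp = sbp - 45, rr = 0.8, id = "fixture") {
  n <- length(t)
  bp_recording(t, rep_len(sbp, n), rep_len(dbp, n), rep_len(rr, n),
               participant_id = id)
}

# flat recording covering the full analysis span at ~0.8 s beats
flat_recording <- function(sbp = 120, dbp = 75, from = -90, to = 125, rr = 0.8,
                           id = "flat") {
  t <- seq(from, to, by = rr)
  beats_recording(t, sbp, dbp, rr, id = id)
}

# archetype with all between-participant spread and beat noise removed
deterministic_archetype <- function(name = "OHYPO") {
  a <- default_archetypes(noise_sd = 0)[[name]]
  a$feature_sd <- c(0, 0, 0)
  a$baseline_sd <- 0
  a$pp_sd <- 0
  a$rr_sd <- 0
  a
}

expect_features_close <- function(fv, targets, tol = 0.5) {
  expect_lt(max(abs(c(fv$early_pct, fv$stab_pct, fv$late_pct) - targets)), tol)
}
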