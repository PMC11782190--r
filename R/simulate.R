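#' Archetype parameters for simulated orthostatic responses
#'
#' Defines one orthostatic morphology archetype: target means/SDs of the
#' three Delta% SBP features, the nadir time of the early drop, the supine
#' baseline distribution, pulse pressure, heart rate, and the beat-level
#' noise model (AR(1) around the response curve).
#'
#' @param name morphology name.
#' @param feature_mean,feature_sd length-3 numeric, Delta% targets
#'   (early, stabilization, late) and their between-participant SDs
#'   (SDs may be 0 for deterministic archetypes).
#' @param t_nadir time of the early-phase nadir plateau (s), in (1, 35).
#' @param baseline_mean,baseline_sd supine SBP (mmHg).
#' @param pp_mean,pp_sd pulse pressure (mmHg); DBP is `SBP - PP`.
#' @param hr_bpm resting heart rate (beats/min).
#' @param rr_sd per-beat RR noise SD (s).
#' @param noise_sd beat-level SBP noise SD (mmHg); 0 gives a noise-free
#'   recording.
#' @param noise_ar AR(1) coefficient of the beat-level noise, in [0, 1).
#' @return list of class `archetype_params`.
#' @export
archetype_params <- function(name, feature_mean, feature_sd, t_nadir = 10,
                             baseline_mean = 116.1, baseline_sd = 19.4,
                             pp_mean = 45.7, pp_sd = 12.0, hr_bpm = 70.2,
                             rr_sd = 0.05, noise_sd = 2, noise_ar = 0.8) {
  stopifnot(length(feature_mean) == 3L, length(feature_sd) == 3L,
            all(feature_sd >= 0), t_nadir > 1, t_nadir < 35,
            baseline_mean > 0, baseline_sd >= 0, pp_mean > 0, hr_bpm > 0,
            rr_sd >= 0, noise_sd >= 0, noise_ar >= 0, noise_ar < 1)
  structure(list(name = name, feature_mean = as.numeric(feature_mean),
                 feature_sd = as.numeric(feature_sd), t_nadir = t_nadir,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 pp_mean = pp_mean, pp_sd = pp_sd, hr_bpm = hr_bpm,
                 rr_sd = rr_sd, noise_sd = noise_sd, noise_ar = noise_ar),
            class = "archetype_params")
}

#' Default morphology archetypes
#'
#' The four archetypes of the study conditions, calibrated to the observed
#' per-group feature means/SDs, supine baselines, pulse pressures and heart
#' rates: iOHYPO (initial deficit), OHYPO (sustained deficit), OHYPER
#' (persistent rise) and NOR (normal orthostatic response).
#'
#' @param noise_sd,noise_ar beat-level noise settings applied to all four
#'   archetypes (defaults 2 mmHg, AR(1) 0.8).
#' @return named list of [archetype_params()].
#' @export
default_archetypes <- function(noise_sd = 2, noise_ar = 0.8) {
  list(
    iOHYPO = archetype_params("iOHYPO", c(-15.2, 0.7, 0.3), c(9.3, 6.6, 7.3),
                              baseline_mean = 119.1, baseline_sd = 18.7,
                              pp_mean = 46.5, pp_sd = 11.6, hr_bpm = 70.3,
                              noise_sd = noise_sd, noise_ar = noise_ar),
    OHYPO = archetype_params("OHYPO", c(-35.6, -15.5, -13.4), c(12.2, 9.5, 10.8),
                             baseline_mean = 115.6, baseline_sd = 18.9,
                             pp_mean = 46.8, pp_sd = 14.1, hr_bpm = 69.2,
                             noise_sd = noise_sd, noise_ar = noise_ar),
    OHYPER = archetype_params("OHYPER", c(2.2, 17.3, 15.6), c(11.3, 9.6, 10.4),
                              baseline_mean = 111.2, baseline_sd = 20.1,
                              pp_mean = 43.6, pp_sd = 10.7, hr_bpm = 70.6,
                              noise_sd = noise_sd, noise_ar = noise_ar),
    NOR = archetype_params("NOR", c(-8.2, 1.6, 1.3), c(7.4, 5.1, 5.3),
                           baseline_mean = 121.4, baseline_sd = 19.6,
                           pp_mean = 47.2, pp_sd = 12.2, hr_bpm = 70.7,
                           noise_sd = noise_sd, noise_ar = noise_ar))
}

# Delta% response curve through plateaus that pin each feature window:
# flat at the early target around the nadir, flat over the 5-s stabilization
# window, flat at the late target across 60-120 s; monotone cubic segments
# in between (no overshoot).
response_curve <- function(early, stab, late, t_nadir) {
  kt <- c(0, 0.5, t_nadir, 38, 42, 60, 120)
  kv <- c(0, early, early, stab, stab, late, late)
  f <- stats::splinefun(kt, kv, method = "monoH.FC")
  function(t) {
    out <- numeric(length(t))
    inside <- t > 0 & t < 120
    out[t >= 120] <- late
    out[inside] <- f(t[inside])
    out
  }
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

# heart-rate recovery profile: RR shortened on standing, slight overshoot
# near 30 s (gives an RR 30:15 ratio above 1), back to resting by 60 s
rr_profile <- function(t) {
  stats::approx(c(0, 3, 20, 30, 60), c(1, 0.88, 0.88, 1.02, 1),
                xout = pmax(t, 0), method = "linear", rule = 2)$y
}

#' Simulate one active-stand recording
#'
#' Beat times accumulate from truncated-normal RR intervals (mean `60 / hr`,
#' scaled by a heart-rate recovery profile after stand onset, SD `rr_sd`,
#' floor 0.3 s). Supine SBP is the baseline plus AR(1) beat noise; standing
#' SBP follows a smooth response curve whose plateaus pin the three feature
#' windows to per-participant Delta% targets drawn from the archetype's
#' means/SDs. DBP is SBP minus a per-participant pulse pressure.
#'
#' @param arch an [archetype_params()].
#' @param participant_id id string.
#' @param supine_span seconds of supine data before stand onset (default 90).
#' @param stand_span seconds of standing data (default 125).
#' @return a [bp_recording] with attributes `true_features` (the drawn
#'   Delta% targets) and `true_group` (the archetype name).
#' @export
simulate_recording <- function(arch, participant_id = "S000",
                               supine_span = 90, stand_span = 125) {
  stopifnot(inherits(arch, "archetype_params"),
            supine_span >= 61, stand_span >= 121)
  targets <- stats::rnorm(3, arch$feature_mean, arch$feature_sd)
  baseline <- rnorm_trunc(1, arch$baseline_mean, arch$baseline_sd, lower = 70)
  # keep the deepest drop above ~35 mmHg systolic
  min_pct <- 100 * (35 / baseline - 1)
  targets <- pmax(targets, min_pct)
  pp <- rnorm_trunc(1, arch$pp_mean, arch$pp_sd, lower = 10,
                    upper = 0.65 * (baseline * (1 + min(0, targets) / 100)))
  curve <- response_curve(targets[1L], targets[2L], targets[3L], arch$t_nadir)
  rr_mean <- 60 / arch$hr_bpm
  t <- numeric(0); rr <- numeric(0)
  now <- -supine_span
  repeat {
    step <- rnorm_trunc(1, rr_mean * rr_profile(now), arch$rr_sd, lower = 0.3)
    now <- now + step
    if (now > stand_span) break
    t <- c(t, now); rr <- c(rr, step)
  }
  n <- length(t)
  noise <- numeric(n)
  if (arch$noise_sd > 0) {
    innov_sd <- arch$noise_sd * sqrt(1 - arch$noise_ar^2)
    noise[1L] <- stats::rnorm(1, 0, arch$noise_sd)
    for (i in seq_len(n - 1L))
      noise[i + 1L] <- arch$noise_ar * noise[i] + stats::rnorm(1, 0, innov_sd)
  }
  sbp <- baseline * (1 + curve(t) / 100) + noise
  pp <- min(pp, min(sbp) - 5)
  rec <- bp_recording(t, sbp, sbp - pp, rr, participant_id = participant_id)
  attr(rec, "true_features") <- targets
  attr(rec, "true_group") <- arch$name
  rec
}

#' Default per-group frailty indicator prevalences
#'
#' Cluster-conditional prevalences of the dichotomized frailty indicators
#' for the simulated cohort, in the order iOHYPO, OHYPO, OHYPER, NOR.
#'
#' @return named list of length-4 probability vectors.
#' @export
default_prevalences <- function() {
  g <- c("iOHYPO", "OHYPO", "OHYPER", "NOR")
  lapply(list(
    adl_compromised = c(0.201, 0.192, 0.315, 0.276),
    cognition_impaired = c(0.656, 0.735, 0.761, 0.791),
    fried_positive = c(0.244, 0.198, 0.324, 0.276),
    slow_gait = c(0.120, 0.119, 0.230, 0.130),
    balance_impaired = c(0.057, 0.057, 0.113, 0.055),
    recent_fall = c(0.177, 0.181, 0.225, 0.252)),
    function(p) stats::setNames(p, g))
}

#' Simulate a cohort of participants with features and frailty covariates
#'
#' Assigns each participant to a morphology group by multinomial draw,
#' draws the three Delta% features from the group archetype (or generates a
#' full beat-to-beat recording when `recordings = TRUE`), and draws frailty
#' indicators from group-conditional prevalences together with demographic
#' and clinical covariates (age 68.1 +/- 7.2 y, 53.7% female, BMI, resting
#' SBP from the archetype baseline, comorbidity/medication flags).
#'
#' @param n cohort size (default 853).
#' @param proportions named mixture proportions over the four groups (must
#'   sum to 1); defaults to the study's final group shares.
#' @param prevalences named list of per-group indicator prevalences, see
#'   [default_prevalences()].
#' @param archetypes named list of [archetype_params()], see
#'   [default_archetypes()].
#' @param recordings if `TRUE`, also simulate full beat-to-beat recordings
#'   and derive features with [extract_features()]; otherwise features are
#'   drawn directly from the archetype feature distribution (fast path).
#' @param seed integer seed (default 0).
#' @return list with `participants` (data frame: id, true group, features,
#'   covariates, indicators) and `recordings` (list of [bp_recording] or
#'   `NULL`).
#' @export
simulate_cohort <- function(n = 853,
                            proportions = c(iOHYPO = 0.245, OHYPO = 0.208,
                                            OHYPER = 0.250, NOR = 0.297),
                            prevalences = default_prevalences(),
                            archetypes = default_archetypes(),
                            recordings = FALSE, seed = 0) {
  stopifnot(n >= 1, abs(sum(proportions) - 1) < 1e-6,
            all(proportions >= 0), !is.null(names(proportions)))
  for (pv in prevalences)
    stopifnot(all(pv >= 0), all(pv <= 1))
  with_seed(seed, {
    groups <- sample(names(proportions), n, replace = TRUE, prob = proportions)
    ids <- sprintf("S%04d", seq_len(n))
    if (recordings) {
      recs <- lapply(seq_len(n), function(i)
        simulate_recording(archetypes[[groups[i]]], participant_id = ids[i]))
      feats <- extract_features_cohort(recs)
      baseline <- feats$baseline
    } else {
      recs <- NULL
      fm <- t(vapply(groups, function(g) {
        a <- archetypes[[g]]
        stats::rnorm(3, a$feature_mean, a$feature_sd)
      }, numeric(3)))
      baseline <- vapply(groups, function(g) {
        a <- archetypes[[g]]
        rnorm_trunc(1, a$baseline_mean, a$baseline_sd, lower = 70)
      }, numeric(1))
      feats <- data.frame(participant_id = ids, baseline = baseline,
                          early_pct = fm[, 1L], stab_pct = fm[, 2L],
                          late_pct = fm[, 3L],
                          early_mmhg = baseline * fm[, 1L] / 100,
                          stab_mmhg = baseline * fm[, 2L] / 100,
                          late_mmhg = baseline * fm[, 3L] / 100,
                          stringsAsFactors = FALSE)
    }
    p <- data.frame(
      participant_id = ids,
      true_group = groups,
      age = rnorm_trunc(n, 68.1, 7.2, lower = 55, upper = 105),
      sex = ifelse(stats::runif(n) < 0.537, "F", "M"),
      bmi = rnorm_trunc(n, 25.3, 4.2, lower = 15, upper = 45),
      resting_sbp = baseline,
      cvd = stats::runif(n) < 0.669,
      diabetes = stats::runif(n) < 0.287,
      antihypertensives = stats::runif(n) < 0.488,
      polypharmacy = stats::runif(n) < 0.321,
      crp_high = stats::runif(n) < 0.349,
      stringsAsFactors = FALSE)
    for (ind in names(prevalences))
      p[[ind]] <- stats::runif(n) < prevalences[[ind]][groups]
    p <- cbind(p, feats[, setdiff(names(feats), "participant_id")])
    list(participants = p, recordings = recs)
  })
}
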