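test_that("recording constructor enforces the beat invariants", {
  expect_s3_class(beats_recording(1:3, c(120, 121, 119)), "bp_recording")
  expect_error(bp_recording(c(1, 2, 2), rep(120, 3), rep(70, 3), rep(0.8, 3)),
               "strictly increasing")
  expect_error(bp_recording(1:2, c(120, 60), c(70, 70), c(0.8, 0.8)),
               "sbp > dbp")
  expect_error(bp_recording(1:2, c(120, 120), c(70, 70), c(0.8, -1)),
               "positive")
  expect_error(bp_recording(numeric(0), numeric(0), numeric(0), numeric(0)),
               "at least one beat")
})

test_that("reading a well-formed file yields the parsed beats", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# stand_onset=0", "t_sec,sbp_mmhg,dbp_mmhg,rr_sec",
               "-1.0,120,70,0.8", "0.2,118,69,0.8", "1.1,115,68,0.9"), path)
  rec <- read_bp_recording(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$sbp, c(120, 118, 115))
  expect_equal(rec$rr[3], 0.9)
})

test_that("malformed or non-monotone files are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# stand_onset=0", "t_sec,sbp_mmhg,dbp_mmhg,rr_sec",
               "1.0,120,70,0.8", "0.5,118,69,0.8"), path)
  expect_error(read_bp_recording(path), "strictly increasing")
  writeLines(c("# stand_onset=0", "t_sec,sbp_mmhg,dbp_mmhg,rr_sec",
               "1.0,120,70,0.8", "2.0,oops,69,0.8"), path)
  expect_error(read_bp_recording(path), "line 2")
  writeLines(c("# stand_onset=0", "t_sec,sbp_mmhg,rr_sec",
               "1.0,120,0.8"), path)
  expect_error(read_bp_recording(path), "dbp_mmhg")
})

test_that("write-read round trip preserves a simulated recording", {
  rec <- simulate_recording(default_archetypes()$NOR, "RT01")
  path <- withr::local_tempfile(fileext = ".csv")
  write_bp_recording(rec, path)
  back <- read_bp_recording(path)
  expect_equal(attr(back, "participant_id"), "RT01")
  expect_equal(back$t, rec$t, tolerance = 1e-8)
  expect_equal(back$sbp, rec$sbp, tolerance = 1e-8)
  expect_equal(back$dbp, rec$dbp, tolerance = 1e-8)
  expect_equal(back$rr, rec$rr, tolerance = 1e-8)
})

test_that("quality screening passes clean recordings and flags anomalies", {
  set.seed(42)
  clean <- simulate_recording(default_archetypes()$iOHYPO)
  expect_true(screen_quality(clean)$passed)

  # flatline: SBP frozen for > 10 s
  t <- seq(-90, 125, by = 0.8)
  sbp <- 120 + sin(t) * 3
  sbp[t >= 20 & t <= 35] <- 117
  rep <- screen_quality(beats_recording(t, sbp))
  expect_false(rep$passed)
  expect_true("flatline" %in% rep$flags)

  # spike: one beat jumping > 40 mmHg vs both neighbours, reverting next beat
  sbp2 <- 120 + sin(t) * 3
  i <- which.min(abs(t - 10))
  sbp2[i] <- sbp2[i] + 45
  rep2 <- screen_quality(beats_recording(t, sbp2))
  expect_true("spike" %in% rep2$flags)

  # short phases
  short <- beats_recording(seq(-30, 125, by = 0.8), 120 + sin(seq(-30, 125, by = 0.8)))
  expect_true("short_phase" %in% screen_quality(short)$flags)

  # gap: > 3 s without a beat
  tg <- c(seq(-90, 50, by = 0.8), seq(55, 125, by = 0.8))
  expect_true("gap" %in% screen_quality(beats_recording(tg, 120 + sin(tg)))$flags)
})

test_that("interpolation is linear, idempotent, and refuses extrapolation", {
  rec <- beats_recording(c(0, 2), c(100, 102))
  s <- interpolate_uniform(rec, c(0, 3))
  expect_equal(s$values, c(100, 101, 102))

  # beats already on the grid are returned unchanged
  rec2 <- beats_recording(0:20, 100 + sin(0:20) * 10)
  s2 <- interpolate_uniform(rec2, c(0, 21))
  expect_equal(s2$values, rec2$sbp)

  expect_error(interpolate_uniform(rec2, c(0, 30)), "coverage")
})

test_that("interpolation matches an independent two-point oracle", {
  set.seed(7)
  for (rep in 1:5) {
    t <- sort(runif(60, -5, 50))
    t <- t[c(TRUE, diff(t) > 1e-3)]
    sbp <- runif(length(t), 90, 150)
    rec <- beats_recording(t, sbp)
    grid <- seq(ceiling(min(t)), floor(max(t)))
    s <- interpolate_uniform(rec, c(grid[1], grid[length(grid)] + 1))
    oracle <- vapply(grid, function(g) {
      i <- max(which(t <= g))
      if (t[i] == g) return(sbp[i])
      sbp[i] + (sbp[i + 1] - sbp[i]) * (g - t[i]) / (t[i + 1] - t[i])
    }, numeric(1))
    expect_equal(s$values, oracle, tolerance = 1e-9)
  }
})

test_that("baseline is the [-60, -30) mean and ignores beats outside it", {
  rec <- flat_recording(sbp = 120)
  s <- interpolate_uniform(rec, c(-60, -29))
  expect_equal(compute_baseline(s), 120)

  # linear ramp 110 -> 120 across the window averages to its midpoint
  t <- seq(-90, 0, by = 0.5)
  ramp <- beats_recording(t, 110 + (t + 60) / 3, dbp = 60)
  sr <- interpolate_uniform(ramp, c(-60, -29))
  grid <- -60:-31
  expect_equal(compute_baseline(sr), mean(110 + (grid + 60) / 3))

  # direct-mean oracle on a random series, and invariance to outside beats
  set.seed(11)
  v <- runif(40, 100, 140)
  s3 <- series_of(-70:-31, v)
  expect_equal(compute_baseline(s3), mean(v[11:40]))
})

test_that("resting indices satisfy the pressure identities", {
  rec <- flat_recording(sbp = 120, dbp = 60)
  ri <- resting_indices(rec)
  expect_equal(ri$pp, 60)
  expect_equal(ri$map, 80)
  expect_equal(ri$hr, 60 / 0.8)
  expect_equal(ri$rr_30_15, 1)  # constant RR

  # cohort linearity: mean PP == mean SBP - mean DBP
  set.seed(3)
  cohort <- lapply(1:6, function(i)
    flat_recording(sbp = runif(1, 100, 140), dbp = runif(1, 55, 85)))
  ris <- lapply(cohort, resting_indices)
  expect_equal(mean(sapply(ris, `[[`, "pp")),
               mean(sapply(ris, `[[`, "sbp")) - mean(sapply(ris, `[[`, "dbp")))
})
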