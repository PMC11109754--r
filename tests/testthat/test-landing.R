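make_fixture_trial <- function(contact = 120L, knee_max = 300L, n = 400L,
                               fs = 200) {
  time <- (seq_len(n) - 1) / fs
  vgrf <- rep(0, n)
  vgrf[contact:n] <- 800
  knee <- rep(5, n)
  knee[contact:knee_max] <- 5 + seq(0, 60, length.out = knee_max - contact + 1)
  knee[(knee_max + 1):n] <- 64
  list(time = time, vgrf = vgrf, knee = knee)
}

test_that("landing phase runs from first contact to maximum knee flexion", {
  fx <- make_fixture_trial()
  phase <- detect_landing_phase(fx$vgrf, fx$knee)
  expect_equal(unname(phase), c(120L, 300L))
  expect_error(detect_landing_phase(rep(5, 100), rep(10, 100)),
               "never crossed")
  # bounce: first crossing wins
  v2 <- fx$vgrf
  v2[100] <- 50
  expect_equal(unname(detect_landing_phase(v2, fx$knee)["start"]), 100L)
  # knee maximum at contact leaves no phase
  expect_error(detect_landing_phase(rep(100, 50), c(60, seq(59, 11, -1))),
               "no landing phase")
})

test_that("zero-phase low-pass keeps DC, kills stop-band, adds no lag", {
  fs <- 200
  t <- seq(0, 2, by = 1 / fs)
  expect_equal(filter_signal(rep(3.3, length(t)), fs, "kinematic"),
               rep(3.3, length(t)), tolerance = 1e-6)
  hum <- sin(2 * pi * 50 * t)
  out <- filter_signal(hum, fs, "kinematic")
  expect_lt(max(abs(out[100:300])), 0.01)
  pulse <- exp(-((t - 1)^2) / (2 * 0.05^2))
  filt <- filter_signal(pulse, fs, cutoff = 10)
  expect_equal(which.max(filt), which.max(pulse))
})

test_that("time normalisation maps windows to exact 101-point curves", {
  ramp <- seq(2, 10, length.out = 57)
  tn <- time_normalize(ramp)
  expect_length(tn, 101)
  expect_equal(tn[1], 2)
  expect_equal(tn[101], 10)
  expect_equal(tn, seq(2, 10, length.out = 101))
  expect_equal(time_normalize(rep(7, 23)), rep(7, 101))
  # interpolation error on a smooth segment vs a dense resample oracle
  x <- sin(seq(0, pi, length.out = 400))
  tn2 <- time_normalize(x, window = c(100, 300))
  oracle <- sin(seq(0, pi, length.out = 400))[seq(100, 300, length.out = 101)]
  expect_lt(max(abs(tn2 - oracle)), 1e-4)
  expect_error(time_normalize(3), "two samples")
})

test_that("joint power is the moment-velocity product", {
  expect_equal(joint_power(2.0, -3.0), -6.0)
  expect_equal(joint_power(rep(0, 10), rnorm(10)), rep(0, 10))
  set.seed(9)
  m <- rnorm(50); w <- rnorm(50)
  expect_equal(sign(joint_power(m, w)), sign(m) * sign(w))
  expect_error(joint_power(1:3, 1:4), "equal length")
})

test_that("energy dissipation integrates only the negative power", {
  time <- seq(0, 0.2, by = 0.001)
  expect_equal(energy_dissipation(rep(-5, length(time)), time), 1.0)
  expect_equal(energy_dissipation(rep(2, length(time)), time), 0)
  t2 <- seq(0, 1, by = 1e-4)
  p <- sin(2 * pi * t2)
  expect_equal(energy_dissipation(p, t2), 1 / pi, tolerance = 1e-6)
  expect_error(energy_dissipation(p, rev(t2)), "increasing")
})

test_that("TED sums the three sagittal joint dissipations", {
  expect_equal(total_energy_dissipation(2, 3, 1), 6)
  expect_equal(total_energy_dissipation(0, 0, 0), 0)
  expect_equal(total_energy_dissipation(1.2, 0.4, 2.1),
               total_energy_dissipation(2.1, 1.2, 0.4))
  expect_error(total_energy_dissipation(1, NA, 2), "required")
})

test_that("extract_summary recovers an embedded summary row within 1%", {
  cal <- cohort_calibration()
  trial <- generate_trial_waveforms(as.list(cal$means))
  s <- extract_summary(trial)
  emb <- attr(trial, "embedded")
  for (v in c("AICA", "AROM", "PVGRF", "PADM", "PKFM", "PHFM", "PAIA",
              "PAIM", "PAF")) {
    expect_lt(abs(s[[v]] - emb[[v]]) / abs(emb[[v]]), 0.01, label = v)
  }
  # all peaks extracted within the detected phase
  phase <- attr(s, "phase")
  expect_lt(phase["start"], phase["end"])
  expect_true(is.finite(s$TED) && s$TED > 0)
})

test_that("a constant-angle trial has zero range of motion", {
  cal <- cohort_calibration()
  row <- as.list(cal$means)
  row$AROM <- 0
  row$PAF <- NA_real_
  trial <- generate_trial_waveforms(row)
  s <- extract_summary(trial)
  expect_lt(abs(s$AROM), 0.2)
  expect_true(is.na(s$PAF))
})

test_that("trial container validates its grid and channels", {
  t <- seq(0, 1, by = 0.005)
  n <- length(t)
  ok <- function(...) trial_time_series(
    time = t, vgrf = rep(0, n), ankle_angle = rep(0, n),
    knee_angle = rep(0, n), hip_angle = rep(0, n),
    ankle_inversion = rep(0, n), ankle_moment = rep(0, n),
    knee_moment = rep(0, n), hip_moment = rep(0, n),
    inversion_moment = rep(0, n), body_mass = 80, ...)
  expect_s3_class(ok(), "trial_time_series")
  expect_equal(attr(ok(), "fs"), 200, tolerance = 1e-9)
  expect_error(trial_time_series(time = t, vgrf = rep(0, n - 1),
                                 ankle_angle = rep(0, n),
                                 knee_angle = rep(0, n),
                                 hip_angle = rep(0, n),
                                 ankle_inversion = rep(0, n),
                                 ankle_moment = rep(0, n),
                                 knee_moment = rep(0, n),
                                 hip_moment = rep(0, n),
                                 inversion_moment = rep(0, n),
                                 body_mass = 80),
               "length")
  tt <- t; tt[5] <- tt[4]
  expect_error(trial_time_series(time = tt, vgrf = rep(0, n),
                                 ankle_angle = rep(0, n),
                                 knee_angle = rep(0, n),
                                 hip_angle = rep(0, n),
                                 ankle_inversion = rep(0, n),
                                 ankle_moment = rep(0, n),
                                 knee_moment = rep(0, n),
                                 hip_moment = rep(0, n),
                                 inversion_moment = rep(0, n),
                                 body_mass = 80),
               "increasing")
})
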