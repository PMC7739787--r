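test_that("default profiles carry the published discipline parameters", {
  pr <- default_profiles()
  expect_named(pr, c("SL", "GS", "SG", "DH"))
  expect_equal(pr$SL$natural_freq, 0.54)
  expect_equal(pr$GS$natural_freq, 0.34)
  expect_equal(pr$SG$natural_freq, 0.25)
  expect_equal(pr$DH$natural_freq, 0.21)
  expect_equal(pr$GS$knee_ol_max, 132)
  expect_equal(pr$DH$turn_duration_mean, 2.5)
  # published per-leg turn-duration envelopes (s): mean +/- 1 SD, IL and OL
  envel <- list(DH = c(2626 - 643, 2394 + 548), SG = c(1998 - 390, 2030 + 387),
                GS = c(1459 - 216, 1477 + 255), SL = c(892 - 134, 922 + 144))
  for (d in names(envel)) {
    expect_gte(pr[[d]]$turn_duration_mean * 1000, envel[[d]][1])
    expect_lte(pr[[d]]$turn_duration_mean * 1000, envel[[d]][2])
  }
  for (d in names(pr)) {
    p <- pr[[d]]
    expect_lt(p$knee_il_min, p$knee_switch_angle)
    expect_lt(p$knee_switch_angle, p$knee_ol_max)
    expect_gte(p$vib_freq_band[1], 2)
    expect_true(all(c(p$iso_plateau_frac_ol, p$iso_plateau_frac_il) >= 0))
    expect_true(all(c(p$iso_plateau_frac_ol, p$iso_plateau_frac_il) < 1))
  }
})

test_that("profile constructor rejects invalid parameterizations", {
  ok <- default_profiles()$GS
  args <- unclass(ok)
  mk <- function(...) {
    a <- utils::modifyList(args, list(...))
    do.call(discipline_profile, a)
  }
  expect_error(mk(turn_duration_mean = -1), "positive")
  expect_error(mk(natural_freq = NaN), "finite")
  expect_error(mk(knee_switch_angle = 50), "knee_il_min")
  expect_error(mk(iso_plateau_frac_ol = 1.2), "plateau")
  expect_error(mk(vib_freq_band = c(1, 15)), "vib_freq_band")
  expect_error(mk(acc_noise_sd = -0.1))
})

test_that("sinusoid phase fractions match the closed form and a dense oracle", {
  # frozen closed-form example: A = 35 deg, f = 0.5 Hz, c = 20 deg/s
  fr <- sinusoid_phase_fractions(35, 0.5, 20)
  expect_equal(unname(fr["iso"]), 11.6439, tolerance = 1e-4)
  expect_equal(unname(fr["ecc"]), 44.1780, tolerance = 1e-4)
  expect_equal(unname(fr["con"]), unname(fr["ecc"]))
  # independent oracle: dense sampling of one period
  t <- seq(0, 2, length.out = 200001)[-1]
  om <- 35 * 2 * pi * 0.5 * cos(2 * pi * 0.5 * t)
  expect_equal(unname(fr["iso"]), 100 * mean(abs(om) <= 20), tolerance = 1e-3)
  # degenerate cases
  expect_equal(unname(sinusoid_phase_fractions(10, 1, 2 * pi * 10)["iso"]), 100)
  expect_equal(unname(sinusoid_phase_fractions(35, 0.5, 0)["iso"]), 0)
  expect_equal(unname(sinusoid_phase_fractions(35, 0.5, 0)["con"]), 50)
})

test_that("phase fractions: conservation and monotonicity properties", {
  set.seed(42)
  for (i in 1:50) {
    A <- runif(1, 5, 90); f <- runif(1, 0.1, 1); c0 <- runif(1, 0, 150)
    fr <- sinusoid_phase_fractions(A, f, c0)
    expect_equal(sum(fr), 100)
  }
  A <- 35; f <- 0.5
  iso_c <- sapply(seq(0, 120, by = 10),
                  function(c0) sinusoid_phase_fractions(A, f, c0)["iso"])
  expect_true(all(diff(iso_c) >= 0))
  iso_f <- sapply(seq(0.1, 1, by = 0.1),
                  function(ff) sinusoid_phase_fractions(A, ff, 20)["iso"])
  expect_true(all(diff(iso_f) <= 0))
  iso_A <- sapply(seq(10, 90, by = 10),
                  function(a) sinusoid_phase_fractions(a, f, 20)["iso"])
  expect_true(all(diff(iso_A) <= 0))
})

test_that("simulate_run is deterministic and validates its profile", {
  s1 <- simulate_run(default_profiles()$GS, n_turns = 6, seed = 1)
  s2 <- simulate_run(default_profiles()$GS, n_turns = 6, seed = 1)
  expect_identical(s1, s2)
  s3 <- simulate_run(default_profiles()$GS, n_turns = 6, seed = 2)
  expect_false(identical(s1$run$knee$values, s3$run$knee$values))
  bad <- default_profiles()$GS
  bad$turn_duration_mean <- -2
  expect_error(simulate_run(bad, n_turns = 6, seed = 1), "positive")
  bad2 <- default_profiles()$GS
  bad2$vib_amp <- Inf
  expect_error(simulate_run(bad2, n_turns = 6, seed = 1), "finite")
  expect_error(simulate_run(default_profiles()$GS, n_turns = 3, seed = 1))
  expect_error(simulate_run(default_profiles()$GS, n_turns = 6, seed = 1, fs = 20))
})

test_that("zero-noise runs equal the exported clean signals everywhere", {
  sim <- cached_sim("GS", n_turns = 8, seed = 3, noiseless = TRUE)
  expect_equal(sim$run$knee$values, sim$truth$clean_angle$values)
  accr <- resultant_acceleration(sim$run$acc_x, sim$run$acc_y, sim$run$acc_z)
  expect_equal(accr$values, sim$truth$raw_accr_clean)
})

test_that("ground truth is internally consistent", {
  for (d in c("SL", "GS", "DH")) {
    sim <- cached_sim(d, n_turns = 12, seed = 5)
    tr <- sim$truth
    expect_true(all(diff(tr$switch_times) > 0))
    expect_true(all(tr$leg_labels[-1] != head(tr$leg_labels, -1)))
    # phase labels are exactly the +/-20 deg/s rule applied to clean velocity
    expect_identical(tr$phase_labels,
                     classify_tripartite(tr$clean_velocity$values, 20))
    # every interior switch coincides with a strict local minimum of the
    # raw clean AccR (the declared time is the vertex of the processed
    # signal; for SL the 1 Hz filter can displace it by a few samples, so
    # the match is checked at detection resolution, 50 ms)
    fs <- 148.15
    sw <- truth_switch_samples(tr, fs)
    a <- tr$raw_accr_clean
    raw_mins <- which(diff(sign(diff(a))) > 0) + 1L
    for (s in sw[3:(length(sw) - 2)]) {
      j <- raw_mins[which.min(abs(raw_mins - s))]
      expect_lte(abs(j - s), round(0.05 * fs))
      expect_true(a[j] < a[j - 1] && a[j] < a[j + 1])
    }
  }
})

test_that("clean OL quasi-isometric fraction matches the calibrated profile", {
  # brute-force counting over clean velocity vs. the profile's calibrated
  # design values (multi-seed calibration documented in the vignette)
  calibrated <- c(SL = 14.5, GS = 30.4, SG = 41.5, DH = 37.5)
  for (d in names(calibrated)) {
    sim <- cached_sim(d, n_turns = 20, seed = 7)
    expect_lt(abs(truth_iso_pct(sim, "OL") - calibrated[[d]]), 2)
  }
})

test_that("ground-truth phase fractions are stable in the sampling rate", {
  a <- cached_sim("GS", n_turns = 12, seed = 9)
  b <- cached_sim("GS", n_turns = 12, seed = 9, fs = 500)
  expect_lt(abs(truth_iso_pct(a, "OL") - truth_iso_pct(b, "OL", fs = 500)), 1)
})

test_that("half-cycle durations reproduce the profile mean within 2%", {
  for (d in c("SL", "DH")) {
    sim <- cached_sim(d, n_turns = 24, seed = 11)
    dur <- diff(sim$truth$switch_times)
    interior <- dur[3:(length(dur) - 2)]
    expect_lt(abs(mean(interior) / default_profiles()[[d]]$turn_duration_mean - 1),
              0.02)
  }
})
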