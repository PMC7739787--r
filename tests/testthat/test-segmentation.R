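test_that("resultant acceleration is the per-sample Euclidean norm", {
  fs <- 148.15
  one <- ts_new(rep(1, 10), fs, "g")
  zero <- ts_new(rep(0, 10), fs, "g")
  expect_equal(resultant_acceleration(one, zero, zero)$values, rep(1, 10))
  expect_equal(resultant_acceleration(ts_new(rep(3, 5), fs, "g"),
                                      ts_new(rep(4, 5), fs, "g"),
                                      ts_new(rep(12, 5), fs, "g"))$values,
               rep(13, 5))
  set.seed(5)
  x <- rnorm(100); y <- rnorm(100); z <- rnorm(100)
  r <- resultant_acceleration(x, y, z)
  oracle <- vapply(1:100, function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2), 0)
  expect_equal(r, oracle)
  expect_error(resultant_acceleration(x, y[1:50], z), "length")
})

test_that("turn switches are recovered exactly on noiseless runs", {
  for (d in c("SL", "GS")) {
    sim <- cached_sim(d, n_turns = 20, seed = 7, noiseless = TRUE)
    accr <- resultant_acceleration(sim$run$acc_x, sim$run$acc_y, sim$run$acc_z)
    det <- detect_turn_switches(accr)
    sw <- truth_switch_samples(sim$truth)
    expect_length(det, length(sw))
    expect_true(all(abs(det - sw) <= 1))
  }
})

test_that("switch detection rejects degenerate inputs", {
  ramp <- ts_new(seq(1, 2, length.out = 2000), 148.15, "g")
  expect_error(detect_turn_switches(ramp), "minima")
})

test_that("segment_cycles cuts half-cycles with alternating legs", {
  sim <- cached_sim("GS", n_turns = 20, seed = 7)
  run <- sim$run
  accr <- resultant_acceleration(run$acc_x, run$acc_y, run$acc_z)
  sw5 <- detect_turn_switches(accr)[1:5]
  seg <- segment_cycles(run, sw5)
  expect_equal(nrow(seg), 4)
  expect_true(all(seg$leg[-1] != head(seg$leg, -1)))
  expect_equal(seg$end_idx[-4], seg$start_idx[-1])       # tiling
  expect_equal(seg$duration_ms, (diff(sw5)) / run$knee$fs * 1000)
  expect_error(segment_cycles(run, sw5[1:2]), "3 switches")
  # full run: legs match the generator truth
  segs <- segment_cycles(run, detect_turn_switches(accr))
  expect_equal(segs$leg, sim$truth$leg_labels)
})

test_that("leg assignment separates clusters and breaks ties deterministically", {
  la <- assign_leg(c(130, 60, 128, 62, 131, 59))
  expect_equal(as.vector(la), c("OL", "IL", "OL", "IL", "OL", "IL"))
  expect_equal(attr(la, "confidence"), 1)
  tie <- assign_leg(rep(90, 4))
  expect_equal(tie[1], "OL")
  expect_lte(attr(tie, "confidence"), 0.5)
})

test_that("trimming excludes first/last cycles, figures and missing data", {
  sim <- cached_sim("GS", n_turns = 20, seed = 7)
  run <- sim$run
  accr <- resultant_acceleration(run$acc_x, run$acc_y, run$acc_z)
  seg <- segment_cycles(run, detect_turn_switches(accr))
  tr <- trim_cycles(seg, run)
  expect_equal(sum(!tr$excluded), 16)                     # 20 - 2*2
  expect_true(all(tr$reason[tr$cycle == 1] == "first_last"))
  expect_true(all(tr$reason[tr$cycle == max(tr$cycle)] == "first_last"))
  # a figure span excludes every overlapping segment
  mid <- seg$start_idx[9] / run$knee$fs
  run_f <- run
  run_f$figure_spans <- data.frame(start_s = mid, end_s = mid + 2,
                                   label = "double")
  tr_f <- trim_cycles(seg, run_f)
  expect_true(any(tr_f$reason == "figure", na.rm = TRUE))
  hit <- which(tr_f$reason == "figure")
  s_t <- tr_f$start_idx[hit] / run$knee$fs
  e_t <- tr_f$end_idx[hit] / run$knee$fs
  expect_true(all(s_t < mid + 2 & e_t > mid))
  # a missing sample excludes its segment
  run_m <- run
  run_m$knee$values[seg$start_idx[9] + 5] <- NA
  tr_m <- trim_cycles(seg, run_m)
  expect_equal(tr_m$reason[9], "missing_data")
  expect_true(tr_m$excluded[9])
})

test_that("time normalization interpolates onto 0-100% inclusively", {
  ramp <- seq(0, 100, length.out = 149)
  expect_equal(time_normalize(ramp), seq(0, 100, by = 1))
  expect_equal(time_normalize(rep(90, 50)), rep(90, 101))
  # analytic resampling oracle for a sinusoid segment at 148.15 Hz
  fs <- 148.15
  t <- seq(0, 1.5, by = 1 / fs)
  x <- 90 + 35 * sin(2 * pi * 0.5 * t)
  got <- time_normalize(x)
  want <- 90 + 35 * sin(2 * pi * 0.5 * seq(0, t[length(t)], length.out = 101))
  expect_lt(max(abs(got - want)), 0.1)
  expect_equal(got[c(1, 101)], x[c(1, length(x))])
  expect_error(time_normalize(c(1, 2, 3)), "short")
})
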