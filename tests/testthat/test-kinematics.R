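test_that("low-pass filter has unit DC gain, a clean passband, and the analytic stopband", {
  dc <- angle_trace(rep(30, 500), fs = 100)
  expect_equal(lowpass_angle(dc)$theta, rep(30, 500), tolerance = 1e-8)

  t <- seq(0, 10, by = 0.01)
  deep <- angle_trace(sin(2 * pi * 1 * t), fs = 100)
  expect_equal(settled_amplitude(lowpass_angle(deep)$theta), 1, tolerance = 0.01)

  # transition band: two-pass magnitude equals the closed-form bilinear
  # Butterworth response
  for (f in c(12, 15)) {
    x <- angle_trace(sin(2 * pi * f * t), fs = 100)
    measured <- settled_amplitude(lowpass_angle(x)$theta)
    expect_equal(measured, butter_lowpass_gain(f, 10, 100, 10)^2,
                 tolerance = 0.02)
  }
  x30 <- angle_trace(sin(2 * pi * 30 * t), fs = 100)
  expect_lt(settled_amplitude(lowpass_angle(x30)$theta), 1e-6)

  expect_error(lowpass_angle(angle_trace(1:30, fs = 20)), "sampling rate")
})

test_that("central differences reproduce analytic derivatives", {
  fs <- 100
  t <- (0:499) / fs
  lin <- angle_trace(10 * t, fs = fs)
  d <- derive_velocity_acceleration(lin)
  expect_equal(d$velocity, rep(10, 500), tolerance = 1e-9)
  expect_equal(d$acceleration[3:498], rep(0, 496), tolerance = 1e-7)

  A <- 20; f <- 1
  sine <- angle_trace(A * sin(2 * pi * f * t), fs = fs)
  ds <- derive_velocity_acceleration(sine)
  expect_equal(max(abs(ds$velocity[3:498])), 2 * pi * f * A, tolerance = 0.01)

  # arbitrary cubic: second derivative is exact at interior points
  theta <- 2 - 3 * t + 0.5 * t^2 + 0.25 * t^3
  cub <- angle_trace(theta, fs = fs)
  dc <- derive_velocity_acceleration(cub)
  expect_equal(dc$acceleration[3:498], (1 + 1.5 * t)[3:498], tolerance = 1e-6)

  expect_error(derive_velocity_acceleration(angle_trace(c(1, 2), fs = 100)),
               "3 samples")
})

test_that("segmentation finds every directional movement and matches brute force", {
  tr <- simulate_angle_trace(rom = 50, n_cycles = 10, cycle_period = 3)
  filt <- lowpass_angle(tr)
  der <- derive_velocity_acceleration(filt)
  cyc <- segment_cycles(filt, der$velocity)
  dirs <- vapply(cyc, `[[`, character(1), "direction")
  expect_equal(sum(dirs == "flexion"), 10)
  expect_equal(sum(dirs == "extension"), 10)

  flat <- angle_trace(rep(12, 400), fs = 100)
  expect_identical(segment_cycles(flat, rep(0, 400)), list())

  # 3-cycle trace with ripple: boundaries equal the exhaustive-scan oracle
  tr3 <- simulate_angle_trace(rom = 50, n_cycles = 3, cycle_period = 3,
                              ripple_amp = 2, ripple_freq = 3)
  filt3 <- lowpass_angle(tr3)
  der3 <- derive_velocity_acceleration(filt3)
  cyc3 <- segment_cycles(filt3, der3$velocity)
  oracle <- brute_segment(der3$velocity)
  expect_equal(length(cyc3), length(oracle))
  for (i in seq_along(cyc3)) {
    expect_equal(cyc3[[i]]$onset_idx, unname(oracle[[i]]["onset"]))
    expect_equal(cyc3[[i]]$offset_idx, unname(oracle[[i]]["offset"]))
  }
})

test_that("cycle features match closed-form values on canonical movements", {
  # smooth raised-cosine movement: exactly one velocity peak
  tr <- simulate_angle_trace(rom = 50, n_cycles = 10, cycle_period = 3)
  kf <- extract_kinematics(tr)
  expect_equal(kf$flexion$nvp, 1)
  expect_equal(kf$extension$nvp, 1)
  expect_equal(kf$flexion$rom, 50, tolerance = 1)

  # untrimmed sinusoidal half-cycle: vmean / vpeak = 2 / pi
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  theta <- -cos(pi * t)
  trace <- angle_trace(theta, fs = fs)
  v <- pi * sin(pi * t)
  a <- pi^2 * cos(pi * t)
  cycle <- list(onset_idx = 1L, offset_idx = length(t), direction = "flexion",
                peak_velocity_ref = max(abs(v)))
  cf <- cycle_features(cycle, trace, v, a)
  expect_equal(cf$vmean / cf$vpeak, 2 / pi, tolerance = 1e-3)
  expect_equal(cf$rom, 2, tolerance = 1e-9)

  expect_error(cycle_features(list(onset_idx = 1L, offset_idx = 2L),
                              trace, v, a), "degenerate")
})

test_that("velocity-peak counts match the analytic zero-crossing oracle", {
  # half-cycle with ripple: theta(t) = sin(pi t) + 0.3 sin(5 pi t) on [0, 1]
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  theta <- sin(pi * t) + 0.3 * sin(5 * pi * t)
  v <- pi * cos(pi * t) + 1.5 * pi * cos(5 * pi * t)
  a <- -pi^2 * sin(pi * t) - 7.5 * pi^2 * sin(5 * pi * t)
  cycle <- list(onset_idx = 2L, offset_idx = length(t) - 1L,
                direction = "flexion", peak_velocity_ref = max(abs(v)))
  cf <- cycle_features(cycle, angle_trace(theta, fs = fs), v, a)
  oracle <- analytic_zero_crossings(
    function(u) -pi^2 * sin(pi * u) - 7.5 * pi^2 * sin(5 * pi * u),
    1 / fs, 1 - 1 / fs)
  expect_equal(cf$nvp, oracle)

  # ripple on the synthetic generator: downstream count matches the analytic
  # derivative of the generating waveform, cycle by cycle
  rom <- 50; period <- 3; ra <- 2; rf <- 3
  tr <- simulate_angle_trace(rom, n_cycles = 3, cycle_period = period,
                             ripple_amp = ra, ripple_freq = rf)
  filt <- lowpass_angle(tr)
  der <- derive_velocity_acceleration(filt)
  cyc <- segment_cycles(filt, der$velocity)
  accel <- function(u)
    (rom / 2) * (2 * pi / period)^2 * cos(2 * pi * u / period) -
      ra * (2 * pi * rf)^2 * sin(2 * pi * rf * u)
  # the one-sided difference stencils at the very first and last samples are
  # not the analytic derivative, so the comparison covers interior movements
  interior <- Filter(function(c) c$onset_idx > 2L &&
                       c$offset_idx < length(filt$theta) - 1L, cyc)
  expect_gte(length(interior), 15)
  for (c in interior) {
    cf <- cycle_features(c, filt, der$velocity, der$acceleration)
    oracle <- analytic_zero_crossings(accel, (c$onset_idx - 1) / 100,
                                      (c$offset_idx - 1) / 100)
    expect_equal(cf$nvp, oracle)
  }
})

test_that("aggregation averages per direction and combines ranges of motion", {
  mk <- function(rom, dir) list(rom = rom, vmean = 10, vpeak = 20, nvp = 1,
                                direction = dir)
  agg <- aggregate_features(list(mk(50, "flexion"), mk(50, "flexion"),
                                 mk(40, "extension"), mk(60, "extension")))
  expect_equal(agg$flexion$rom, 50)
  expect_equal(agg$extension$rom, 50)
  expect_equal(agg$rom_combined$flexion_extension, 100)

  agg2 <- aggregate_features(list(mk(25, "flexion"), mk(27, "extension")))
  expect_equal(agg2$rom_combined$flexion_extension, 52)

  # one-sided axis: flagged missing, no silent zero
  agg3 <- aggregate_features(list(mk(30, "right_rotation")))
  expect_true("left_rotation" %in% agg3$missing_directions)
  expect_null(agg3$rom_combined$rotation)
})

test_that("joint position error recovers injected errors under noise", {
  set.seed(14)
  noisy <- lapply(1:20, function(i)
    simulate_jpe_trial(5, noise_sd = 0.5, seed = 100 + i))
  jpe <- compute_jpe(noisy, list())$jpe_right
  # rest-window averaging: SE of one trial error ~ noise_sd * sqrt(2/n_window)
  se <- 0.5 * sqrt(2 / 75) / sqrt(20)
  expect_lt(abs(jpe - 5), 4 * se + 0.01)

  expect_error(compute_jpe(list(angle_trace(1:10, fs = 100)), list()),
               "rest windows")
})

test_that("kinematic features obey offset, shift and smoothness-ordering invariants", {
  tr <- simulate_angle_trace(rom = 45, n_cycles = 3, cycle_period = 2.5,
                             ripple_amp = 1.5, ripple_freq = 4)
  kf <- extract_kinematics(tr)
  # offset invariance
  shifted <- angle_trace(tr$theta + 13, fs = tr$fs, axis = tr$axis)
  kf2 <- extract_kinematics(shifted)
  expect_equal(kf2$flexion$rom, kf$flexion$rom, tolerance = 1e-6)
  expect_equal(kf2$flexion$nvp, kf$flexion$nvp)
  # vmean never exceeds vpeak
  for (d in c("flexion", "extension")) expect_lte(kf[[d]]$vmean, kf[[d]]$vpeak)
  # smoothness ordering, stated in the regime each quantity is defined for:
  # while the ripple is small enough that movement segmentation is unchanged,
  # reducing its amplitude never increases the per-movement velocity-peak
  # count; once the ripple reverses velocity and fragments the recording into
  # extra movements, the per-movement mean is no longer comparable, but the
  # total crossing count over all movements still never increases
  feats <- lapply(c(2, 1, 0.5, 0.2, 0.1, 0.02, 0), function(a)
    extract_kinematics(simulate_angle_trace(
      rom = 45, n_cycles = 3, cycle_period = 2.5,
      ripple_amp = a, ripple_freq = 4)))
  total <- vapply(feats, function(k)
    k$flexion$nvp * k$flexion$n_cycles + k$extension$nvp * k$extension$n_cycles,
    numeric(1))
  expect_true(all(diff(total) <= 0))
  fixed_seg <- Filter(function(k)
    k$flexion$n_cycles == 3 && k$extension$n_cycles == 3, feats)
  expect_gte(length(fixed_seg), 3)
  per_move <- vapply(fixed_seg, function(k) k$flexion$nvp, numeric(1))
  expect_true(all(diff(per_move) <= 0))
})
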