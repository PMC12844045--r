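test_that("HSPP generator matches its calibration: mean, peak time, peak height", {
  h <- generate_hspp(period = 0.8, target_mean = 0.9, dt = 0.004)
  expect_equal(mean(h$flow_lpm), 0.9, tolerance = 1e-12)
  expect_equal(h$time_s[which.max(h$flow_lpm)], 0.24)
  # solve mean = b + (P - b) * (2/pi) * s for P at b = -0.4785, s = 0.6
  expect_equal(max(h$flow_lpm), -0.4785 + (0.9 + 0.4785) * pi / 1.2,
               tolerance = 2e-3)
  expect_equal(max(h$flow_lpm), 3.13, tolerance = 1e-2)
  expect_true(profile_is_feasible(h))
  # same calibration holds on the coarser corpus grid
  h01 <- generate_hspp(dt = 0.01)
  expect_equal(mean(h01$flow_lpm), 0.9, tolerance = 1e-12)
  expect_equal(h01$time_s[which.max(h01$flow_lpm)], 0.24)
})

test_that("degenerate HSPP with baseline at the target mean is constant", {
  h <- generate_hspp(baseline = 0.9, target_mean = 0.9)
  expect_equal(h$flow_lpm, rep(0.9, 200), tolerance = 1e-12)
})

test_that("HSPP amplitude beyond the pump ceiling is rejected", {
  expect_error(generate_hspp(target_mean = 3.5), "ceiling")
})

test_that("waveform families are mean-normalized, feasible and seed-reproducible", {
  fams <- c("hspp", "sine", "pulmonary_artery", "composite_gaussian",
            "gaussian_exponential")
  for (fam in fams) {
    for (seed in c(1, 11, 2025)) {
      spec <- waveform_spec(fam, target_mean = 1.1)
      p1 <- generate_waveform(spec, seed = seed)
      p2 <- generate_waveform(spec, seed = seed)
      expect_identical(p1$flow_lpm, p2$flow_lpm)
      expect_equal(mean(p1$flow_lpm), 1.1,
                   tolerance = 1e-9 * max(1, abs(1.1)))
      expect_true(profile_is_feasible(p1))
      expect_true(all(is.finite(p1$flow_lpm)))
    }
  }
  expect_error(waveform_spec("triangle"))
})

test_that("zero-amplitude sine collapses to a constant at the target mean", {
  p <- generate_waveform(waveform_spec("sine", amplitude = 0), seed = 3)
  expect_equal(p$flow_lpm, rep(0.9, 80), tolerance = 1e-12)
})

test_that("normalize_mean shifts additively and preserves shape", {
  p <- flow_profile(c(0, 0.01), c(1, 2))
  out <- normalize_mean(p, 0.9)
  expect_equal(out$flow_lpm, c(0.4, 1.4))
  expect_equal(mean(out$flow_lpm), 0.9)
  const <- normalize_mean(flow_profile(c(0, 0.01), c(2, 2)), 0.9)
  expect_equal(const$flow_lpm, c(0.9, 0.9))
  idem <- normalize_mean(out, 0.9)
  expect_equal(idem$flow_lpm, out$flow_lpm)
})

test_that("project_step scales by dq_max and clips at the operating bounds", {
  expect_equal(project_step(1.0, 1.0), 1.4)
  expect_equal(project_step(4.9, 1.0), 5.0)
  expect_equal(project_step(0.7, 0), 0.7)
  expect_equal(project_step(-0.3, -1), -0.5)
  expect_error(project_step(1, 1.2), "squash")
})

test_that("project_profile clamps sequentially and is idempotent", {
  p <- flow_profile(c(0, 0.004), c(0, 1.0))
  out <- project_profile(p)
  expect_equal(out$flow_lpm, c(0, 0.4))
  # already-feasible profiles are untouched; double projection is projection
  h <- generate_hspp()
  expect_equal(project_profile(h)$flow_lpm, h$flow_lpm)
  r <- flow_profile((0:99) * 0.004, cumsum(runif(100, -1, 1)))
  once <- project_profile(r)
  expect_equal(project_profile(once)$flow_lpm, once$flow_lpm)
  expect_lte(max(abs(diff(once$flow_lpm))), 0.4 + 1e-12)
  expect_error(project_profile(flow_profile(c(0, 0.01), c(0, 1))), "grid")
})

test_that("feature derivatives match closed forms on analytic waveforms", {
  # constant: all derived features vanish
  f <- compute_features(constant_profile(1.2))
  expect_equal(f$dq, rep(0, 200))
  expect_equal(f$d2q, rep(0, 200))
  expect_equal(f$kappa, rep(0, 200))
  # sine at fine dt: curvature of sin(2*pi*t) in closed form
  dt <- 0.001
  t <- seq(0, 1 - dt, by = dt)
  p <- flow_profile(t, sin(2 * pi * t), period = 1)
  f <- compute_features(p)
  dq_true <- 2 * pi * cos(2 * pi * t)
  d2q_true <- -(2 * pi)^2 * sin(2 * pi * t)
  kap_true <- abs(d2q_true) / (1 + dq_true^2)^1.5
  interior <- 3:(length(t) - 2)
  expect_lt(max(abs(f$kappa - kap_true)[interior] /
                  pmax(kap_true[interior], 1)), 1e-3)
  expect_lt(max(abs(f$dq - dq_true) / max(abs(dq_true))), 1e-4)
  expect_error(compute_features(flow_profile(c(0, 1), c(0, 1))), "3 samples")
})

test_that("resampling interpolates linearly, preserves the mean, and is identity at equal dt", {
  h <- generate_hspp()
  expect_identical(resample_profile(h, 0.004)$flow_lpm, h$flow_lpm)
  const <- resample_profile(constant_profile(0.7), 0.002)
  expect_equal(unique(const$flow_lpm), 0.7)
  # ramp halved: new midpoints are neighbour means
  ramp <- flow_profile((0:9) * 0.01, 1:10, period = 0.1)
  half <- resample_profile(ramp, 0.005)
  expect_equal(half$flow_lpm[2], mean(ramp$flow_lpm[1:2]))
  expect_equal(half$flow_lpm[4], mean(ramp$flow_lpm[2:3]))
  # mean conservation under a non-integer refinement
  odd <- resample_profile(generate_hspp(), 0.003)
  expect_equal(mean(odd$flow_lpm), 0.9, tolerance = 1e-6 * 0.9)
})

test_that("waveform CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  h <- generate_hspp()
  write_waveform_csv(h, path)
  back <- read_waveform_csv(path)
  expect_equal(back$flow_lpm, h$flow_lpm, tolerance = 1e-9)
  expect_equal(back$time_s, h$time_s, tolerance = 1e-9)
})

test_that("time_grid and pump_limits enforce their invariants", {
  g <- time_grid(dt = 0.004, period = 0.8)
  expect_equal(g$n_steps, 200L)
  expect_error(time_grid(dt = -1, period = 1))
  expect_error(time_grid(dt = 0.01, n_steps = 50, period = 0.8))
  expect_error(pump_limits(q_min = 2, q_max = 1))
  expect_error(pump_limits(dq_max = 0))
})
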