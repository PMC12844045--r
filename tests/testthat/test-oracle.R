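test_that("oxygen content and transfer rate follow the content formula", {
  expect_equal(oxygen_content(blood_gas(0, 0, 0)), 0)
  expect_equal(oxygen_content(blood_gas(10, 100, 100)), 137.14)
  # affine in pO2 with slope 0.0314 at fixed hb/so2
  po2 <- c(0, 40, 100, 400)
  cont <- oxygen_content(blood_gas(rep(12, 4), rep(80, 4), po2))
  expect_equal(diff(cont) / diff(po2), rep(0.0314, 3))
  pre <- blood_gas(10, 65, 40)
  post <- blood_gas(10, 100, 150)
  expect_equal(o2_transfer_rate(pre, post), 50.354)
  expect_equal(o2_transfer_rate(post, pre), -o2_transfer_rate(pre, post))
  expect_equal(o2_transfer_rate(pre, pre), 0)
  expect_error(blood_gas(10, 120, 40))
  expect_error(blood_gas(-1, 50, 40))
})

test_that("content formula agrees with an independent hand computation on random draws", {
  withr::with_seed(99, {
    hb <- runif(1000, 5, 20)
    so2 <- runif(1000, 0, 100)
    po2 <- runif(1000, 0, 500)
  })
  expected <- 13.4 * hb * so2 / 100 + 0.0314 * po2   # written out afresh
  expect_equal(oxygen_content(blood_gas(hb, so2, po2)), expected)
})

test_that("hemolysis power law evaluates and is monotone", {
  expect_equal(hemolysis_fraction(0, 5), 0)
  expect_equal(hemolysis_fraction(100, 1), 3.62e-5 * 100^2.416,
               tolerance = 1e-12)
  expect_equal(hemolysis_fraction(100, 1), 2.459, tolerance = 1e-3)
  taus <- seq(0, 200, by = 10)
  expect_true(all(diff(hemolysis_fraction(taus, 1)) > 0))
  ts <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(hemolysis_fraction(50, ts)) > 0))
  expect_error(hemolysis_fraction(-1, 1))
})

test_that("wall shear is proportional to |flow|", {
  op <- oracle_params(c_tau = 10)
  expect_equal(wall_shear(0, op), 0)
  expect_equal(wall_shear(2, op), 20)
  expect_equal(wall_shear(-2, op), wall_shear(2, op))
})

test_that("oracle episode OTR matches the closed form for constant flow", {
  op <- oracle_params()
  lab <- oracle_labels(constant_profile(0.9), op)
  k <- op$k_ref * 0.9^op$m_exp
  expect_equal(lab$otr_episode, op$c_art * (1 - exp(-k / 0.9)),
               tolerance = 1e-10)
  expect_equal(lab$hem_episode, sum(lab$labels$hem_inst))
  expect_true(all(lab$labels$otr_inst >= 0))
})

test_that("pulsatility enhancement off makes labels depend on |q| only", {
  op0 <- oracle_params(gamma_p = 1e-12)  # parameters must stay positive
  h <- generate_hspp()
  const_same_q <- oracle_labels(constant_profile(0.9), op0)
  k <- op0$k_ref * 0.9^op0$m_exp
  expect_equal(unique(round(const_same_q$labels$otr_inst, 9)),
               round(op0$c_art * (1 - exp(-k / 0.9)), 9))
  # without the bonus, a pulsatile profile's labels depend on |q| alone
  h0 <- oracle_labels(h, op0)
  u <- pmax(abs(h$flow_lpm), op0$q_floor)
  expect_equal(h0$labels$otr_inst,
               op0$c_art * (1 - exp(-op0$k_ref * u^op0$m_exp / u)),
               tolerance = 1e-9)
  # with enhancement on, a pulsatile profile at the same mean transfers more
  op <- oracle_params()
  for (fam in c("sine", "pulmonary_artery", "gaussian_exponential")) {
    p <- generate_waveform(waveform_spec(fam, target_mean = 0.9), seed = 5)
    expect_gt(oracle_labels(p, op)$otr_episode,
              oracle_labels(constant_profile(0.9), op)$otr_episode)
  }
  expect_gt(oracle_labels(h, op)$otr_episode,
            oracle_labels(constant_profile(0.9), op)$otr_episode)
})

test_that("cycle hemolysis is non-decreasing under pointwise |q| increase", {
  h <- generate_hspp(target_mean = 0.9, baseline = 0.1)
  scaled <- flow_profile(h$time_s, h$flow_lpm * 1.2, projected = TRUE)
  expect_gte(oracle_labels(scaled)$hem_episode,
             oracle_labels(h)$hem_episode)
})

test_that("degenerate flows are rejected by the oracle", {
  expect_error(oracle_labels(constant_profile(0)), "positive flow")
  ramp <- flow_profile(c(0, 0.004), c(0, 3))  # violates the step limit
  expect_error(oracle_labels(ramp), "pump limits")
})

test_that("NIH follows the ASTM normalization", {
  expect_equal(nih(0, 1, 40, 0.9, 240), 0)
  expect_equal(nih(0.05, 1, 40, 0.9, 240), 0.05 * 1 * 0.6 * 100 / (0.9 * 240))
  expect_equal(nih(0.05, 1, 40, 0.9, 240), 0.0138889, tolerance = 1e-5)
  expect_equal(nih(0.05, 1, 40, 0.9, 480), nih(0.05, 1, 40, 0.9, 240) / 2)
  expect_error(nih(0.05, 1, 40, 0, 240))
})

test_that("label files round-trip through CSV + JSON sidecar", {
  lab <- oracle_labels(generate_hspp())
  path <- withr::local_tempfile(fileext = ".csv")
  write_oracle_labels(lab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$otr_inst, lab$labels$otr_inst, tolerance = 1e-9)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$otr_episode, lab$otr_episode, tolerance = 1e-9)
})
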