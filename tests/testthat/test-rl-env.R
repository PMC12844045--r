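test_that("reset yields the documented initial state", {
  env <- pulse_env(env_config())
  s <- env_reset(env)
  expect_equal(s, c(0, 0, 0, 0, 0, 0, 0, 1))
  expect_length(s, 8)
  env2 <- pulse_env(env_config(q_init = 0.9))
  expect_equal(env_reset(env2)[1], 0.9)
})

test_that("state assembly normalizes time progress and remaining demand", {
  cfg <- env_config()
  demand <- cfg$q_tar * cfg$period
  s <- build_state(0.9, rep(0.9, 5), 100L, demand / 2, cfg)
  expect_equal(s[7], 0.5)
  expect_equal(s[8], 0.5)
  s_end <- build_state(0.9, rep(0.9, 5), 200L, demand, cfg)
  expect_equal(s_end[7], 1)
  expect_equal(s_end[8], 0)
  expect_equal(build_state(0, rep(0, 5), 0L, 0, cfg)[8], 1)
  expect_error(build_state(0, rep(0, 5), 300L, 0, cfg))
})

test_that("reward decomposes exactly into its weighted terms", {
  w <- reward_weights(eta_max = 60)
  # all penalties off, full oxygenation: reward is beta_o
  rt <- reward_terms(q_trace = rep(0.9, 10), a_trace = rep(0, 10),
                     eta_t = 60, d_t = 0, is_terminal = FALSE, w = w)
  expect_equal(rt$reward, w$beta_o)
  # window-mean deviation enters with weight lambda_a
  rt2 <- reward_terms(rep(1.1, 10), rep(0, 10), 0, 0, FALSE, w)
  expect_equal(unname(rt2$terms["Pa"]), -0.2, tolerance = 1e-12)
  # terminal flow within tolerance escapes the terminal penalty
  rt3 <- reward_terms(c(rep(0.9, 9), 0.05), rep(0, 10), 0, 0, TRUE, w)
  expect_equal(unname(rt3$terms["Pe"]), 0)
  rt4 <- reward_terms(c(rep(0.9, 9), 0.5), rep(0, 10), 0, 0, TRUE, w)
  expect_equal(unname(rt4$terms["Pe"]), -0.5)
  expect_error(reward_terms(1, 1, 1, 1, FALSE, reward_weights(eta_max = NULL)))
})

test_that("stepping conserves the reward decomposition and episode accounting", {
  env <- pulse_env(env_config())
  env_reset(env)
  w <- env$cfg$weights
  n <- 0L
  withr::with_seed(1, {
    repeat {
      sr <- env_step(env, runif(1, -1, 1))
      n <- n + 1L
      recomposed <- w$beta_o * sr$info$Ro + w$beta_d * sr$info$Rd +
        w$lambda_a * sr$info$Pa + w$lambda_s * sr$info$Ps +
        w$lambda_e * sr$info$Pe
      expect_equal(sr$reward, recomposed, tolerance = 1e-12)
      if (sr$done) break
    }
  })
  expect_equal(n, 200L)
  expect_error(env_step(env, 0), "finished")
})

test_that("reward is monotone in oxygen transfer and hemolysis", {
  w <- reward_weights(eta_max = 60)
  base <- reward_terms(rep(0.9, 10), rep(0, 10), 30, 0.001, FALSE, w)$reward
  more_o2 <- reward_terms(rep(0.9, 10), rep(0, 10), 40, 0.001, FALSE, w)$reward
  more_dmg <- reward_terms(rep(0.9, 10), rep(0, 10), 30, 0.002, FALSE, w)$reward
  expect_gt(more_o2, base)
  expect_lt(more_dmg, base)
})

test_that("zero actions hold the flow at its initial value all episode", {
  env <- pulse_env(env_config(q_init = 0.7))
  env_reset(env)
  for (i in 1:200) sr <- env_step(env, 0)
  expect_true(sr$done)
  expect_equal(unique(env$q_trace), 0.7)
})

test_that("no action sequence can leave the pump's constraint set", {
  # vectorized fuzz over 10^4 episodes of the same action-to-flow recursion
  n_ep <- 10000L
  limits <- pump_limits()
  withr::with_seed(42, {
    q <- runif(n_ep, limits$q_min, limits$q_max)
    for (t in 1:200) {
      a <- runif(n_ep, -1, 1)
      q_new <- project_step(q, a, limits)
      expect_true(all(q_new >= limits$q_min - 1e-12))
      expect_true(all(q_new <= limits$q_max + 1e-12))
      expect_true(all(abs(q_new - q) <= limits$dq_max + 1e-12))
      q <- q_new
    }
  })
  # and a handful of full environment episodes exercise the same projection
  env <- pulse_env(env_config())
  withr::with_seed(7, {
    for (k in 1:5) {
      env_reset(env)
      repeat if (env_step(env, runif(1, -1, 1))$done) break
      expect_true(all(env$q_trace >= limits$q_min - 1e-12))
      expect_true(all(env$q_trace <= limits$q_max + 1e-12))
      expect_lte(max(abs(diff(env$q_trace))), limits$dq_max + 1e-12)
    }
  })
})

test_that("action sequences map to projected profiles and back", {
  cfg <- env_config()
  zero <- rollout_to_profile(rep(0, 200), cfg)
  expect_equal(unique(zero$flow_lpm), 0)
  stairs <- rollout_to_profile(rep(1, 200), cfg)
  expect_equal(stairs$flow_lpm[1:3], c(0.4, 0.8, 1.2))
  expect_equal(max(stairs$flow_lpm), 5.0)
  expect_true(profile_is_feasible(stairs))
  withr::with_seed(3, a <- runif(200, -1, 1) * 0.9)
  prof <- rollout_to_profile(a, cfg)
  round_trip <- rollout_to_profile(profile_to_actions(prof, cfg), cfg)
  expect_equal(round_trip$flow_lpm, prof$flow_lpm, tolerance = 1e-12)
  expect_error(rollout_to_profile(rep(0, 10), cfg), "200")
})

test_that("oracle and surrogate backends expose the same interface and agree", {
  ds <- small_dataset()
  cfg_s <- small_surrogate_cfg()
  sur <- list(otr = train_surrogate(ds, cfg_s, "otr"),
              hem = train_surrogate(ds, cfg_s, "hem"))
  env_o <- pulse_env(env_config(q_init = 0.9))
  env_s <- pulse_env(env_config(q_init = 0.9, backend = "surrogate",
                                surrogates = sur))
  withr::with_seed(11, acts <- 0.5 * sin(seq(0, 6 * pi, length.out = 200)))
  run <- function(env) {
    env_reset(env)
    vapply(acts, function(a) suppressWarnings(env_step(env, a))$info$eta_t, 0)
  }
  eta_o <- run(env_o)
  eta_s <- run(env_s)
  # agreement within a few times the net's coarse training error
  expect_lt(mean(abs(eta_o - eta_s)) / mean(eta_o), 0.15)
  expect_error(env_config(backend = "surrogate"), "surrogates")
})
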