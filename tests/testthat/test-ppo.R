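test_that("GAE matches a brute-force expansion on short episodes", {
  # hand-unrolled case: rewards [1,1], values [0,0], gamma .9, lambda .8
  g <- compute_gae(c(1, 1), c(0, 0), c(FALSE, TRUE), gamma = 0.9,
                   gae_lambda = 0.8)
  expect_equal(g$advantages, c(1 + 0.9 * 0.8 * 1, 1))
  expect_equal(g$returns, g$advantages)
  withr::with_seed(21, {
    for (n in 1:5) {
      for (rep in 1:20) {
        r <- rnorm(n)
        v <- rnorm(n)
        gam <- runif(1, 0.5, 1)
        lam <- runif(1, 0, 1)
        got <- compute_gae(r, v, c(rep(FALSE, n - 1), TRUE), gam, lam)
        expect_equal(got$advantages, gae_bruteforce(r, v, gam, lam),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("GAE limits: zero inputs and the Monte-Carlo case", {
  z <- compute_gae(rep(0, 4), rep(0, 4), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(z$advantages, rep(0, 4))
  r <- c(1, 2, 3)
  v <- c(0.5, -0.2, 0.1)
  mc <- compute_gae(r, v, c(FALSE, FALSE, TRUE), gamma = 1, gae_lambda = 1)
  expect_equal(mc$advantages, rev(cumsum(rev(r))) - v)
  expect_error(compute_gae(1:3, 1:2, c(FALSE, TRUE)))
})

test_that("clipped objective reproduces analytic cases and the unclipped limit", {
  adv <- c(2, -1, 0.5)
  expect_equal(clipped_objective(rep(0, 3), rep(0, 3), adv), mean(adv))
  # rho = 1.5, A = 1: clip binds from above at 1.2
  expect_equal(clipped_objective(log(1.5), 0, 1, clip_eps = 0.2), 1.2)
  # rho = 0.5, A = -1: min(-0.5, -0.8) = -0.8
  expect_equal(clipped_objective(log(0.5), 0, -1, clip_eps = 0.2), -0.8)
  withr::with_seed(5, {
    new_lp <- rnorm(50)
    old_lp <- rnorm(50)
    a <- rnorm(50)
  })
  expect_equal(clipped_objective(new_lp, old_lp, a, clip_eps = 1e9),
               mean(exp(new_lp - old_lp) * a))
})

test_that("entropy curriculum follows the printed three-phase schedule", {
  sch <- train_schedule(total_steps = 1.4e6, scale = 1)
  expect_equal(entropy_coef_at(sch, 0), 0.05)
  expect_equal(entropy_coef_at(sch, 4e5), 0.05)
  expect_equal(entropy_coef_at(sch, 8e5), 0.03)  # right-continuous switch
  expect_equal(entropy_coef_at(sch, 1e6), 0.03)
  expect_equal(entropy_coef_at(sch, 1.2e6), 0.01)
  expect_equal(entropy_coef_at(sch, 1.4e6), 0.01)
  desk <- train_schedule()  # scale 1/100
  expect_equal(entropy_coef_at(desk, 7999), 0.05)
  expect_equal(entropy_coef_at(desk, 8000), 0.03)
  expect_equal(entropy_coef_at(desk, 12000), 0.01)
  expect_error(train_schedule(entropy_steps = c(0, 5, 5)))
})

test_that("policy forward passes are deterministic and thread hidden state", {
  pol <- policy_init(policy_config(lstm_units = 16, head_hidden = 8),
                     state_dim = 8, seed = 4)
  withr::with_seed(8, states <- matrix(rnorm(48), 6, 8))
  f1 <- policy_forward(pol, states)
  f2 <- policy_forward(pol, states)
  expect_identical(f1$mean, f2$mean)
  hid <- NULL
  stepped <- numeric(6)
  vals <- numeric(6)
  for (t in 1:6) {
    f <- policy_forward(pol, states[t, ], hid)
    hid <- f$hidden
    stepped[t] <- f$mean
    vals[t] <- f$value
  }
  expect_equal(stepped, f1$mean, tolerance = 1e-6)
  expect_equal(vals, f1$value, tolerance = 1e-6)
  expect_true(is.finite(policy_forward(pol, rep(0, 8))$value))
  expect_error(policy_forward(pol, rep(0, 5)))
})

test_that("analytic PPO gradients match finite differences", {
  pol <- policy_init(policy_config(lstm_units = 6, head_hidden = 4),
                     state_dim = 3, seed = 2)
  withr::with_seed(14, {
    mk <- function() list(states = matrix(rnorm(15), 5, 3), u = rnorm(5),
                          old_logp = rnorm(5, -1), adv = rnorm(5),
                          ret = rnorm(5))
    eps_list <- list(mk(), mk())
  })
  g <- pulseopt:::ppo_grad_cpp(pol, eps_list, c(1L, 2L), 0.2, 0.5, 0.01)
  h <- 1e-6
  for (nm in c("Wx", "Wh", "b", "Wa1", "Wa2", "Wc1", "Wc2", "log_std")) {
    p_hi <- pol
    p_hi[[nm]][1, 1] <- p_hi[[nm]][1, 1] + h
    p_lo <- pol
    p_lo[[nm]][1, 1] <- p_lo[[nm]][1, 1] - h
    fd <- (pulseopt:::ppo_loss_cpp(p_hi, eps_list, c(1L, 2L), 0.2, 0.5, 0.01) -
             pulseopt:::ppo_loss_cpp(p_lo, eps_list, c(1L, 2L), 0.2, 0.5,
                                     0.01)) / (2 * h)
    expect_equal(g$grads[[nm]][1, 1], fd, tolerance = 1e-4)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  sch <- train_schedule(total_steps = 1600, rollout_steps = 800)
  a1 <- train_agent(env_config(), sch, seed = 5)
  a2 <- train_agent(env_config(), sch, seed = 5)
  expect_identical(a1$history$reward, a2$history$reward)
  expect_identical(a1$policy$Wx, a2$policy$Wx)
  expect_equal(nrow(a1$history), 1600 / 200)
})

test_that("desk-scale training improves the policy for most shipped seeds", {
  improved <- vapply(1:4, function(s) {
    sch <- train_schedule(total_steps = 6000, scale = 6 / 1400)
    ag <- train_agent(env_config(), sch, seed = s)
    g <- glance(ag)
    g$final_phase_mean > g$first_phase_mean
  }, TRUE)
  expect_gte(sum(improved), 3)
})

test_that("extracted profiles are feasible and repeatable", {
  sch <- train_schedule(total_steps = 2000, rollout_steps = 1000)
  ag <- train_agent(env_config(), sch, seed = 1)
  p1 <- suppressWarnings(extract_optimized_profile(ag))
  p2 <- suppressWarnings(extract_optimized_profile(ag))
  expect_identical(p1$flow_lpm, p2$flow_lpm)
  expect_true(profile_is_feasible(p1))
  expect_equal(nrow(p1), 200)
})
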