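#' Multi-objective reward weights
#'
#' Coefficients of the per-step reward
#' `r_t = beta_o*Ro + beta_d*Rd + lambda_a*Pa + lambda_s*Ps + lambda_e*Pe`,
#' where `Ro = eta_t / eta_max` rewards oxygenation, `Rd = -kappa_norm * D_t`
#' penalizes the instantaneous hemolysis increment, `Pa` penalizes deviation
#' of the sliding-window flow mean from the target, `Ps` penalizes the mean
#' magnitude of recent flow accelerations, and `Pe` is a terminal penalty on
#' a non-zero final flow.
#'
#' @param beta_o,beta_d,lambda_a,lambda_s,lambda_e Term coefficients. The
#'   default `lambda_s` is scaled to accelerations expressed in L/min per
#'   second (which reach ~100 at the pump slew limit), keeping the smoothness
#'   penalty commensurate with the oxygenation reward.
#' @param kappa_norm Hemolysis normalization coefficient.
#' @param eta_max Theoretical maximum transfer rate (mL O2 / L); `NULL` means
#'   "use the oracle's content ceiling `c_art`".
#' @param q_tar Target mean flow (L/min).
#' @param w_window Sliding-window width W (steps) shared by `Pa` and `Ps`.
#' @param tau_tol Terminal flow tolerance (L/min).
#' @return A list of class `reward_weights`.
#' @export
reward_weights <- function(beta_o = 1.0, beta_d = 1.0, kappa_norm = 10,
                           lambda_a = 4.0, lambda_s = 0.002, lambda_e = 1.0,
                           eta_max = NULL, q_tar = 0.9, w_window = 5L,
                           tau_tol = 0.1) {
  if (!is.null(eta_max) && eta_max <= 0) abort("`eta_max` must be positive.")
  if (w_window < 1) abort("`w_window` must be at least 1.")
  if (tau_tol < 0) abort("`tau_tol` must be non-negative.")
  structure(list(beta_o = beta_o, beta_d = beta_d, kappa_norm = kappa_norm,
                 lambda_a = lambda_a, lambda_s = lambda_s,
                 lambda_e = lambda_e, eta_max = eta_max, q_tar = q_tar,
                 w_window = as.integer(w_window), tau_tol = tau_tol),
            class = "reward_weights")
}

#' Episodic environment configuration
#'
#' One episode builds one pulsation period: `n_steps` control intervals of
#' `dt_ctrl` seconds (200 x 4 ms = 0.8 s, i.e. 1.25 Hz, by default).
#'
#' @param dt_ctrl Control interval (s).
#' @param n_steps Steps per episode.
#' @param q_tar Target mean flow (L/min).
#' @param limits A [pump_limits()] object.
#' @param weights A [reward_weights()] object.
#' @param history_n Length of the flow-history slice in the state (n = 5).
#' @param q_init Initial flow (L/min).
#' @param backend `"oracle"` (analytic labels) or `"surrogate"` (trained
#'   networks; supply `surrogates`).
#' @param oracle,hemolysis Oracle parameter objects.
#' @param surrogates For the surrogate backend, `list(otr = , hem = )` of
#'   `pulse_surrogate` models.
#' @param d_floor Floor applied to the remaining-demand state component.
#' @return A list of class `env_config`.
#' @export
env_config <- function(dt_ctrl = 0.004, n_steps = 200L, q_tar = 0.9,
                       limits = pump_limits(), weights = reward_weights(),
                       history_n = 5L, q_init = 0,
                       backend = c("oracle", "surrogate"),
                       oracle = oracle_params(), hemolysis = hemolysis_params(),
                       surrogates = NULL, d_floor = -1) {
  backend <- match.arg(backend)
  if (history_n < 1) abort("`history_n` must be at least 1.")
  if (backend == "surrogate" &&
      (is.null(surrogates$otr) || is.null(surrogates$hem))) {
    abort("Surrogate backend needs `surrogates = list(otr = , hem = )`.")
  }
  weights$eta_max <- weights$eta_max %||% oracle$c_art
  structure(list(dt_ctrl = dt_ctrl, n_steps = as.integer(n_steps),
                 q_tar = q_tar, limits = limits, weights = weights,
                 history_n = as.integer(history_n), q_init = q_init,
                 backend = backend, oracle = oracle, hemolysis = hemolysis,
                 surrogates = surrogates, d_floor = d_floor,
                 period = dt_ctrl * n_steps),
            class = "env_config")
}

#' Assemble the agent's observation
#'
#' State layout: current flow, the last `history_n` flows, normalized time
#' progress `step_idx / n_steps`, and normalized remaining flow demand
#' `(q_tar * T - sum(q_k * dt)) / (q_tar * T)` (floored at `d_floor`). Length
#' is `history_n + 3` (8 with the defaults).
#'
#' @param q_t Current flow (L/min).
#' @param q_hist Last `history_n` flows, most recent last.
#' @param step_idx Steps taken so far.
#' @param cumulative_flow Running `sum(q_k * dt_ctrl)` (L/min * s).
#' @param cfg An [env_config()].
#' @return Numeric state vector.
#' @export
build_state <- function(q_t, q_hist, step_idx, cumulative_flow, cfg) {
  if (step_idx > cfg$n_steps) abort("`step_idx` exceeds the episode length.")
  demand <- cfg$q_tar * cfg$period
  d_remain <- max((demand - cumulative_flow) / demand, cfg$d_floor)
  c(q_t, q_hist, step_idx / cfg$n_steps, d_remain)
}

#' Decompose the per-step reward into its terms
#'
#' Returns each term together with the weighted total; the total always
#' equals the weighted sum of the terms exactly (this is the invariant the
#' environment's `info` field exposes).
#'
#' The smoothness window covers the accelerations `a_k` for
#' `k = t-W+1 .. t-1` (the current step excluded), with `a_k` the realized
#' per-step flow change rate in L/min per second.
#'
#' @param q_trace Flows visited so far (including the current step).
#' @param a_trace Realized flow accelerations so far (L/min per s).
#' @param eta_t Instantaneous oxygen transfer (mL O2 / L), non-negative.
#' @param d_t Instantaneous hemolysis increment (%), non-negative.
#' @param is_terminal Is this the final step of the episode?
#' @param w A [reward_weights()] object (with `eta_max` resolved).
#' @return A list with `reward` and `terms` (named: Ro, Rd, Pa, Ps, Pe).
#' @export
reward_terms <- function(q_trace, a_trace, eta_t, d_t, is_terminal, w) {
  if (is.null(w$eta_max) || w$eta_max <= 0) abort("`eta_max` must be positive.")
  if (eta_t < 0 || d_t < 0) abort("`eta_t` and `d_t` must be non-negative.")
  W <- w$w_window
  Ro <- eta_t / w$eta_max
  Rd <- -w$kappa_norm * d_t
  Pa <- -abs(mean(tail(q_trace, W)) - w$q_tar)
  n <- length(a_trace)
  prev <- if (n >= 2) a_trace[seq(max(1L, n - W + 1L), n - 1L)] else numeric(0)
  Ps <- -sum(abs(prev)) / W
  Q_T <- q_trace[length(q_trace)]
  Pe <- if (is_terminal && abs(Q_T) > w$tau_tol) -abs(Q_T) else 0
  terms <- c(Ro = Ro, Rd = Rd, Pa = Pa, Ps = Ps, Pe = Pe)
  reward <- w$beta_o * Ro + w$beta_d * Rd + w$lambda_a * Pa +
    w$lambda_s * Ps + w$lambda_e * Pe
  list(reward = reward, terms = terms)
}

# Instantaneous (eta_t, d_t) from the causal trace so far. The flow
# derivative is the one-step-delayed central difference (q_t - q_{t-2})/(2 dt):
# it is causal, matches the periodic central difference used for whole-cycle
# labelling, and is blind to period-2 dither (alternating the flow every
# single 4-ms step is numerical chatter, not boundary-layer-scale pulsation).
backend_labels <- function(cfg, q_new, q_prev, q_prev2) {
  dt <- cfg$dt_ctrl
  dq <- (q_new - q_prev2) / (2 * dt)
  if (cfg$backend == "oracle") {
    op <- cfg$oracle
    u <- max(abs(q_new), op$q_floor)
    k <- op$k_ref * u^op$m_exp * (1 + op$gamma_p * tanh(abs(dq) / op$a_ref))
    eta <- op$c_art * (1 - exp(-k / u))
    d <- hemolysis_fraction(wall_shear(q_new, op), dt, cfg$hemolysis)
  } else {
    d2q <- (q_new - 2 * q_prev + q_prev2) / dt^2
    kappa <- abs(d2q) / (1 + dq^2)^1.5
    x <- matrix(c(q_new, dq, d2q, kappa), nrow = 1,
                dimnames = list(NULL, c("q", "dq", "d2q", "kappa")))
    eta <- max(suppressWarnings(predict(cfg$surrogates$otr, x)$.pred), 0)
    d <- max(suppressWarnings(predict(cfg$surrogates$hem, x)$.pred), 0)
  }
  list(eta_t = eta, d_t = d)
}

#' Create an episodic flow-control environment
#'
#' The environment holds mutable episode state; interact with it through
#' [env_reset()] and [env_step()].
#'
#' @param cfg An [env_config()].
#' @return An object of class `pulse_env`.
#' @export
pulse_env <- function(cfg = env_config()) {
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  e$done <- TRUE
  class(e) <- "pulse_env"
  e
}

#' @export
print.pulse_env <- function(x, ...) {
  cat(sprintf("<pulse_env: %d x %g ms steps, q_tar = %g L/min, backend = %s>\n",
              x$cfg$n_steps, x$cfg$dt_ctrl * 1000, x$cfg$q_tar,
              x$cfg$backend))
  invisible(x)
}

#' Reset the environment to the start of an episode
#'
#' @param env A [pulse_env()].
#' @return The initial state vector: flow at `q_init`, history padded with
#'   `q_init`, zero time progress, full remaining demand.
#' @export
env_reset <- function(env) {
  cfg <- env$cfg
  env$q <- cfg$q_init
  env$hist <- rep(cfg$q_init, cfg$history_n)
  env$step_idx <- 0L
  env$cum_flow <- 0
  env$q_trace <- numeric(0)
  env$a_trace <- numeric(0)
  env$done <- FALSE
  build_state(env$q, env$hist, 0L, 0, cfg)
}

#' Advance the environment by one constrained control step
#'
#' The normalized action is mapped through [project_step()] (scaled by
#' `dq_max`, clipped to the pump bounds), the backend supplies the
#' instantaneous oxygen-transfer and hemolysis labels for the updated trace,
#' and the multi-objective reward is assembled via [reward_terms()].
#'
#' @param env A [pulse_env()]; must have been reset and not be finished.
#' @param a_norm Normalized action in `[-1, 1]`.
#' @return A list of class `step_result`: `state`, `reward`, `done`, `info`
#'   (with `eta_t`, `d_t`, `q` and each reward term).
#' @export
env_step <- function(env, a_norm) {
  if (isTRUE(env$done)) abort("Episode finished; call env_reset() first.")
  cfg <- env$cfg
  q_prev <- env$q
  q_prev2 <- if (length(env$q_trace) >= 2) {
    env$q_trace[length(env$q_trace) - 1]
  } else {
    cfg$q_init
  }
  q_new <- project_step(q_prev, a_norm, cfg$limits)
  env$q_trace <- c(env$q_trace, q_new)
  env$a_trace <- c(env$a_trace, (q_new - q_prev) / cfg$dt_ctrl)
  env$step_idx <- env$step_idx + 1L
  env$cum_flow <- env$cum_flow + q_new * cfg$dt_ctrl
  env$done <- env$step_idx >= cfg$n_steps

  lab <- backend_labels(cfg, q_new, q_prev, q_prev2)
  rw <- reward_terms(env$q_trace, env$a_trace, lab$eta_t, lab$d_t,
                     env$done, cfg$weights)

  env$hist <- c(env$hist[-1], q_new)
  env$q <- q_new
  state <- build_state(q_new, env$hist, env$step_idx, env$cum_flow, cfg)
  structure(list(state = state, reward = rw$reward, done = env$done,
                 info = c(list(eta_t = lab$eta_t, d_t = lab$d_t, q = q_new),
                          as.list(rw$terms))),
            class = "step_result")
}

#' Convert an action sequence to its realized flow profile
#'
#' Iterates [project_step()] from `q_init`, so the result is feasible by
#' construction and flagged as projected.
#'
#' @param actions Normalized actions, length `n_steps`.
#' @param cfg An [env_config()].
#' @return A `flow_profile` on the control grid.
#' @export
rollout_to_profile <- function(actions, cfg = env_config()) {
  if (length(actions) != cfg$n_steps) {
    abort(sprintf("Need exactly %d actions.", cfg$n_steps))
  }
  q <- numeric(cfg$n_steps)
  prev <- cfg$q_init
  for (i in seq_along(actions)) {
    prev <- project_step(prev, actions[i], cfg$limits)
    q[i] <- prev
  }
  flow_profile((seq_len(cfg$n_steps) - 1) * cfg$dt_ctrl, q,
               period = cfg$period, projected = TRUE, family = "rollout")
}

#' Recover the implied actions of a feasible profile
#'
#' Inverse of [rollout_to_profile()] for profiles reachable from `q_init`
#' under the step limit.
#'
#' @param profile A feasible `flow_profile` on the control grid.
#' @param cfg An [env_config()].
#' @return Normalized actions in `[-1, 1]`.
#' @export
profile_to_actions <- function(profile, cfg = env_config()) {
  q <- profile$flow_lpm
  a <- diff(c(cfg$q_init, q)) / cfg$limits$dq_max
  if (any(abs(a) > 1 + 1e-9)) {
    abort("Profile is not reachable from `q_init` under the step limit.")
  }
  pmin(pmax(a, -1), 1)
}
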