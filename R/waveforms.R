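#' Check a profile against pump limits
#'
#' A profile is feasible ("projected") when every sample lies within the pump's
#' absolute flow bounds and successive samples differ by no more than the
#' per-step limit scaled to the profile's grid, `dq_max * dt / dt_ctrl`.
#' Continuity across the cyclic wrap is not required here; the environment's
#' terminal flow constraint is what encourages repeatable cycles.
#'
#' @param profile A `flow_profile`.
#' @param limits A [pump_limits()] object.
#' @return Logical scalar.
#' @export
profile_is_feasible <- function(profile, limits = pump_limits()) {
  q <- profile$flow_lpm
  dt <- profile_dt(profile)
  step_cap <- limits$dq_max * dt / limits$dt_ctrl
  in_bounds <- all(q >= limits$q_min - 1e-12) && all(q <= limits$q_max + 1e-12)
  in_bounds && all(abs(diff(q)) <= step_cap + 1e-12)
}

mark_projected <- function(profile, limits) {
  attr(profile, "projected") <- profile_is_feasible(profile, limits)
  profile
}

#' Generate the half-sine pulse profile (HSPP)
#'
#' The baseline pulsatile waveform: a half-sine systolic lobe of duration
#' `systolic_fraction * period` rising from a constant diastolic baseline, with
#' the lobe amplitude solved so the period-average flow equals `target_mean`.
#' The peak occurs at `systolic_fraction * period / 2`. With the defaults
#' (period 0.8 s, mean 0.9 L/min, systolic fraction 0.6, baseline
#' −0.4785 L/min) the pulse peaks at about 3.13 L/min near 0.24 s.
#'
#' @param period Pulsation period (s).
#' @param target_mean Required period-average flow (L/min).
#' @param systolic_fraction Fraction of the period occupied by the lobe,
#'   in (0, 1).
#' @param baseline Diastolic flow held between lobes (L/min).
#' @param dt Sample interval (s).
#' @param limits A [pump_limits()] object used for the feasibility flag and the
#'   amplitude check.
#'
#' @return A `flow_profile` with mean exactly `target_mean` on its grid.
#' @export
#' @examples
#' hspp <- generate_hspp()
#' mean(hspp$flow_lpm)  # 0.9
generate_hspp <- function(period = 0.8, target_mean = 0.9,
                          systolic_fraction = 0.6, baseline = -0.4785,
                          dt = 0.004, limits = pump_limits()) {
  if (!(systolic_fraction > 0 && systolic_fraction < 1)) {
    abort("`systolic_fraction` must be in (0, 1).")
  }
  if (baseline < limits$q_min) abort("`baseline` is below the pump floor.")
  # continuous-time mean: m = b + (P - b) * (2/pi) * s  =>  solve for peak P
  peak <- baseline + (target_mean - baseline) * pi / (2 * systolic_fraction)
  if (peak > limits$q_max + 1e-12) {
    abort(sprintf(
      "Required lobe peak %.3f L/min exceeds the pump ceiling %.2f L/min.",
      peak, limits$q_max))
  }
  grid <- time_grid(dt = dt, period = period)
  t <- (seq_len(grid$n_steps) - 1L) * dt
  lobe <- period * systolic_fraction
  q <- ifelse(t < lobe, baseline + (peak - baseline) * sin(pi * t / lobe),
              baseline)
  prof <- flow_profile(t, q, period = period, family = "hspp")
  prof <- normalize_mean(prof, target_mean)  # absorb the tiny grid-sum residual
  mark_projected(prof, limits)
}

#' Specify a member of a waveform family
#'
#' Families mirror the corpus used to train the surrogates: half-sine pulses,
#' sine waves of varying amplitude and frequency, pulmonary-artery-like double
#' humps, composite Gaussian profiles, and Gaussian-rise/exponential-decay
#' pulses. Family parameters omitted here are sampled reproducibly from the
#' seed at generation time.
#'
#' @param family One of `"hspp"`, `"sine"`, `"pulmonary_artery"`,
#'   `"composite_gaussian"`, `"gaussian_exponential"`.
#' @param target_mean Required period-average flow (L/min).
#' @param period Period (s).
#' @param ... Family-specific parameters (see Details).
#'
#' @details Family parameters (all optional): sine — `amplitude` (L/min),
#'   `cycles` (integer periods per window), `phase` (rad); pulmonary_artery —
#'   `a1` (systolic amplitude), `a2_frac` (dicrotic amplitude as a fraction of
#'   `a1`), centers/widths as fractions of the period; composite_gaussian —
#'   `n_lobes`, `amps`, `centers`, `widths`; gaussian_exponential — `amp`,
#'   `t_peak`, `sigma`, `tau_decay`. Amplitude defaults scale with
#'   `target_mean` so flows stay positive and within pump slew limits.
#'
#' @return A list of class `waveform_spec`.
#' @export
waveform_spec <- function(family = c("hspp", "sine", "pulmonary_artery",
                                     "composite_gaussian",
                                     "gaussian_exponential"),
                          target_mean = 0.9, period = 0.8, ...) {
  family <- match.arg(family)
  if (period <= 0) abort("`period` must be positive.")
  structure(list(family = family, target_mean = target_mean, period = period,
                 params = list(...)),
            class = "waveform_spec")
}

draw_or <- function(params, name, draw) params[[name]] %||% draw()

#' Generate a waveform from a family specification
#'
#' Deterministic given `(spec, seed)`: unspecified family parameters are drawn
#' from the seed, the shape is sampled on the grid, and the profile is
#' mean-normalized to `spec$target_mean` by an additive shift.
#'
#' @param spec A [waveform_spec()].
#' @param seed Integer seed fixing any sampled parameters.
#' @param dt Sample interval (s); the surrogate corpus uses 0.01 s.
#' @param limits A [pump_limits()] object; a normalized profile leaving
#'   `[q_min, q_max]` raises a constraint-infeasibility error.
#'
#' @return A `flow_profile` with attribute `params` recording the realized
#'   family parameters (for the dataset manifest).
#' @export
generate_waveform <- function(spec, seed = 1L, dt = 0.01,
                              limits = pump_limits()) {
  if (!inherits(spec, "waveform_spec")) abort("`spec` must be a waveform_spec.")
  T <- spec$period
  m <- spec$target_mean
  grid <- time_grid(dt = dt, period = T)
  t <- (seq_len(grid$n_steps) - 1L) * dt
  p <- spec$params

  realized <- withr::with_seed(seed, {
    switch(spec$family,
      hspp = {
        sf <- draw_or(p, "systolic_fraction", function() runif(1, 0.4, 0.7))
        bl <- draw_or(p, "baseline", function() runif(1, 0.1, 0.5) * m)
        list(systolic_fraction = sf, baseline = bl)
      },
      sine = {
        amp <- draw_or(p, "amplitude", function() runif(1, 0.1, 0.7) * m)
        cyc <- draw_or(p, "cycles", function() sample(1:3, 1))
        ph <- draw_or(p, "phase", function() runif(1, 0, 2 * pi))
        list(amplitude = amp, cycles = cyc, phase = ph)
      },
      pulmonary_artery = {
        a1 <- draw_or(p, "a1", function() runif(1, 1.5, 3) * m)
        list(a1 = a1,
             a2_frac = draw_or(p, "a2_frac", function() runif(1, 0.2, 0.35)),
             c1 = draw_or(p, "c1", function() runif(1, 0.18, 0.26)),
             s1 = draw_or(p, "s1", function() runif(1, 0.06, 0.09)),
             c2 = draw_or(p, "c2", function() runif(1, 0.42, 0.5)),
             s2 = draw_or(p, "s2", function() runif(1, 0.04, 0.06)))
      },
      composite_gaussian = {
        k <- draw_or(p, "n_lobes", function() sample(2:3, 1))
        list(n_lobes = k,
             amps = draw_or(p, "amps", function() runif(k, 0.4, 1.2) * m),
             centers = draw_or(p, "centers", function() runif(k, 0.1, 0.9)),
             widths = draw_or(p, "widths", function() runif(k, 0.06, 0.12)))
      },
      gaussian_exponential = {
        list(amp = draw_or(p, "amp", function() runif(1, 1.5, 3) * m),
             t_peak = draw_or(p, "t_peak", function() runif(1, 0.15, 0.3)),
             sigma = draw_or(p, "sigma", function() runif(1, 0.04, 0.08)),
             tau_decay = draw_or(p, "tau_decay",
                                 function() runif(1, 0.08, 0.2)))
      })
  })

  q0 <- switch(spec$family,
    hspp = {
      prof <- generate_hspp(period = T, target_mean = m,
                            systolic_fraction = realized$systolic_fraction,
                            baseline = realized$baseline, dt = dt,
                            limits = limits)
      prof$flow_lpm
    },
    sine = realized$amplitude *
      sin(2 * pi * realized$cycles * t / T + realized$phase),
    pulmonary_artery = {
      g <- function(c, s) exp(-((t / T - c)^2) / (2 * s^2))
      realized$a1 * g(realized$c1, realized$s1) +
        realized$a1 * realized$a2_frac * g(realized$c2, realized$s2)
    },
    composite_gaussian = {
      q <- numeric(length(t))
      for (j in seq_len(realized$n_lobes)) {
        q <- q + realized$amps[j] *
          exp(-((t / T - realized$centers[j])^2) / (2 * realized$widths[j]^2))
      }
      q
    },
    gaussian_exponential = {
      tp <- realized$t_peak * T
      rise <- exp(-((t - tp)^2) / (2 * (realized$sigma * T)^2))
      decay <- exp(-(t - tp) / (realized$tau_decay * T))
      realized$amp * ifelse(t <= tp, rise, decay)
    })

  prof <- flow_profile(t, q0, period = T, family = spec$family)
  prof <- normalize_mean(prof, m)
  if (min(prof$flow_lpm) < limits$q_min - 1e-12 ||
      max(prof$flow_lpm) > limits$q_max + 1e-12) {
    abort(sprintf(
      "Normalized %s profile leaves pump bounds [%.2f, %.2f] L/min.",
      spec$family, limits$q_min, limits$q_max))
  }
  prof <- mark_projected(prof, limits)
  attr(prof, "params") <- realized
  prof
}

#' Mean-normalize a flow profile
#'
#' Shifts the whole profile by a constant so its grid mean equals `q_tar`. The
#' additive shift preserves the pulse shape exactly (a multiplicative rescale
#' would distort it).
#'
#' @param profile A `flow_profile`.
#' @param q_tar Target mean flow (L/min).
#' @return The shifted `flow_profile` (feasibility flag cleared; re-validate
#'   with [profile_is_feasible()] if needed).
#' @export
normalize_mean <- function(profile, q_tar) {
  profile <- as_flow_profile(profile)
  shift <- q_tar - mean(profile$flow_lpm)
  out <- flow_profile(profile$time_s, profile$flow_lpm + shift,
                      period = attr(profile, "period"),
                      family = attr(profile, "family"))
  attr(out, "params") <- attr(profile, "params")
  out
}

#' Apply one constrained actuation step
#'
#' Maps a normalized control signal in `[-1, 1]` to the next flow value: the
#' signal scales the pump's maximum per-step flow variation `dq_max`, and the
#' result is clipped to the operating bounds.
#'
#' @param q_prev Previous flow (L/min); vectorized.
#' @param a_norm Normalized action in `[-1, 1]`; vectorized.
#' @param limits A [pump_limits()] object.
#' @return Next flow value(s) (L/min).
#' @export
#' @examples
#' project_step(1.0, 1.0)  # 1.4: a full-scale action adds dq_max = 0.4 L/min
#' project_step(4.9, 1.0)  # 5.0: clipped at the ceiling
project_step <- function(q_prev, a_norm, limits = pump_limits()) {
  if (any(!is.finite(a_norm)) || any(a_norm < -1 | a_norm > 1)) {
    abort("`a_norm` must lie in [-1, 1]; squash the raw action first.")
  }
  pmin(pmax(q_prev + a_norm * limits$dq_max, limits$q_min), limits$q_max)
}

#' Project a whole profile onto the pump constraint set
#'
#' Sequentially clamps each step change to `±dq_max` and each value to
#' `[q_min, q_max]`. The operation is idempotent. The profile must already be
#' on the control grid (`dt == dt_ctrl`); resample first otherwise.
#'
#' @inheritParams normalize_mean
#' @param limits A [pump_limits()] object.
#' @return A feasible `flow_profile` flagged as projected.
#' @export
project_profile <- function(profile, limits = pump_limits()) {
  profile <- as_flow_profile(profile)
  dt <- profile_dt(profile)
  if (abs(dt - limits$dt_ctrl) > 1e-9) {
    abort("Profile is not on the control grid; resample to `dt_ctrl` first.")
  }
  q <- profile$flow_lpm
  out <- numeric(length(q))
  out[1] <- min(max(q[1], limits$q_min), limits$q_max)
  for (i in seq_along(q)[-1]) {
    lo <- max(out[i - 1] - limits$dq_max, limits$q_min)
    hi <- min(out[i - 1] + limits$dq_max, limits$q_max)
    out[i] <- min(max(q[i], lo), hi)
  }
  res <- flow_profile(profile$time_s, out, period = attr(profile, "period"),
                      projected = TRUE, family = attr(profile, "family"))
  res
}

#' Differentiate a flow profile into surrogate features
#'
#' Computes the first derivative, second derivative, and curvature of the flow
#' profile by central finite differences with periodic wraparound (profiles are
#' one period of a cyclic waveform, so wraparound avoids boundary artifacts).
#' Curvature uses the plane-curve formula on the nondimensionalized curve
#' (flow in units of 1 L/min against time in units of 1 s):
#' `kappa = |q''| / (1 + q'^2)^(3/2)`.
#'
#' @inheritParams normalize_mean
#' @return A tibble with columns `time_s`, `q`, `dq` (L/min per s), `d2q`
#'   (L/min per s^2), `kappa` (dimensionless, non-negative).
#' @export
compute_features <- function(profile) {
  profile <- as_flow_profile(profile)
  q <- profile$flow_lpm
  n <- length(q)
  if (n < 3L) abort("Need at least 3 samples to differentiate.")
  dt <- profile_dt(profile)
  qp <- c(q[-1], q[1])    # q_{i+1}, periodic
  qm <- c(q[n], q[-n])    # q_{i-1}, periodic
  dq <- (qp - qm) / (2 * dt)
  d2q <- (qp - 2 * q + qm) / dt^2
  kappa <- abs(d2q) / (1 + dq^2)^1.5
  tibble::tibble(time_s = profile$time_s, q = q, dq = dq, d2q = d2q,
                 kappa = kappa)
}

#' Resample a profile to a new grid spacing
#'
#' Linear interpolation on the periodic extension of the waveform, bridging the
#' 0.01 s surrogate grid and the 4 ms control grid. The grid mean is preserved
#' exactly by re-centering after interpolation (the re-centering shift is zero
#' for integer refinements and otherwise of interpolation-error size).
#'
#' @inheritParams normalize_mean
#' @param dt_new New sample interval (s).
#' @return A `flow_profile` on the new grid with the same period and mean.
#' @export
resample_profile <- function(profile, dt_new) {
  profile <- as_flow_profile(profile)
  if (dt_new <= 0) abort("`dt_new` must be positive.")
  dt <- profile_dt(profile)
  if (abs(dt_new - dt) < 1e-12) return(profile)
  T <- attr(profile, "period") %||% (dt * nrow(profile))
  grid_new <- time_grid(dt = dt_new, period = T)
  t_new <- (seq_len(grid_new$n_steps) - 1L) * dt_new
  t_ext <- c(profile$time_s, T)               # periodic closure
  q_ext <- c(profile$flow_lpm, profile$flow_lpm[1])
  q_new <- approx(t_ext, q_ext, xout = t_new, method = "linear")$y
  q_new <- q_new + (mean(profile$flow_lpm) - mean(q_new))
  flow_profile(t_new, q_new, period = T, family = attr(profile, "family"))
}
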