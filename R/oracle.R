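#' Blood-gas sample
#'
#' A tibble of blood-gas measurements: hemoglobin concentration `hb` (g/dL),
#' oxygen saturation `so2` (%), and oxygen partial pressure `po2` (mmHg).
#'
#' @param hb Hemoglobin concentration (g/dL), non-negative.
#' @param so2 Oxygen saturation (%), in \[0, 100\].
#' @param po2 Oxygen partial pressure (mmHg), non-negative.
#' @return A tibble of class `blood_gas`.
#' @export
blood_gas <- function(hb, so2, po2) {
  if (any(hb < 0)) abort("`hb` must be non-negative.")
  if (any(so2 < 0 | so2 > 100)) abort("`so2` must be in [0, 100].")
  if (any(po2 < 0)) abort("`po2` must be non-negative.")
  out <- tibble::tibble(hb = hb, so2 = so2, po2 = po2)
  class(out) <- c("blood_gas", class(out))
  out
}

#' Total oxygen content of blood
#'
#' Hemoglobin-bound plus dissolved oxygen:
#' `1.34 mL/g * 10 * hb * so2/100 + 0.0314 * po2`, i.e.
#' `13.4 * hb * so2/100 + 0.0314 * po2` in mL O2 per L blood.
#'
#' @param bg A [blood_gas()] tibble (or any data frame with columns `hb`,
#'   `so2`, `po2`).
#' @return Oxygen content (mL O2 per L blood), vectorized over rows.
#' @export
#' @examples
#' oxygen_content(blood_gas(hb = 10, so2 = 100, po2 = 100))  # 137.14
oxygen_content <- function(bg) {
  bg <- blood_gas(bg$hb, bg$so2, bg$po2)  # re-validate
  13.4 * bg$hb * bg$so2 / 100 + 0.0314 * bg$po2
}

#' Oxygen transfer rate between two blood-gas samples
#'
#' Content difference across the oxygenator, `C(post) - C(pre)`, in mL O2 per
#' L blood; negative values indicate deoxygenation.
#'
#' @param pre_bg,post_bg [blood_gas()] samples drawn before/after the device.
#' @return mL O2 per L blood, vectorized over rows.
#' @export
o2_transfer_rate <- function(pre_bg, post_bg) {
  oxygen_content(post_bg) - oxygen_content(pre_bg)
}

#' Hemolysis power-law constants
#'
#' Constants of the shear-stress/exposure-time power law for the released
#' hemoglobin fraction. Defaults are the widely used Giersiepen-family
#' constants (`C = 3.62e-5` %, `a = 0.785`, `b = 2.416`); all are
#' configurable.
#'
#' @param c_coef Scale constant (% per Pa^b s^a).
#' @param a_exp Exposure-time exponent.
#' @param b_exp Shear-stress exponent.
#' @return A list of class `hemolysis_params`.
#' @export
hemolysis_params <- function(c_coef = 3.62e-5, a_exp = 0.785, b_exp = 2.416) {
  if (c_coef <= 0 || a_exp <= 0 || b_exp <= 0) {
    abort("All hemolysis constants must be positive.")
  }
  structure(list(c_coef = c_coef, a_exp = a_exp, b_exp = b_exp),
            class = "hemolysis_params")
}

#' Released-hemoglobin fraction under shear
#'
#' Power law `dHb/Hb (%) = C * tau^b * t_exp^a` for blood exposed to shear
#' stress `tau` for time `t_exp`.
#'
#' @param tau Shear stress (Pa), non-negative; vectorized.
#' @param t_exp Exposure time (s), non-negative; vectorized.
#' @param params A [hemolysis_params()] object.
#' @return Hemolysed fraction (%).
#' @export
#' @examples
#' hemolysis_fraction(100, 1)  # ~2.459 %
hemolysis_fraction <- function(tau, t_exp, params = hemolysis_params()) {
  if (any(tau < 0) || any(t_exp < 0)) {
    abort("`tau` and `t_exp` must be non-negative.")
  }
  params$c_coef * tau^params$b_exp * t_exp^params$a_exp
}

#' Pseudo-CFD oracle constants
#'
#' Parameters of the analytic gas-transfer stand-in used to label waveforms
#' (in place of a full CFD model). The oracle combines a quasi-steady
#' Sherwood-type mass-transfer coefficient (`k_ref`, `m_exp`), a saturating
#' pulsatility-enhancement term in the flow derivative (`gamma_p`, `a_ref`;
#' the boundary-layer-disruption analogy), residence-time saturation through a
#' per-pass exponential, a saturation-limited content gain `c_art`, and a
#' flow-proportional wall-shear proxy `c_tau`.
#'
#' @param k_ref Mass-transfer scale (L/min).
#' @param m_exp Flow exponent of the transfer coefficient.
#' @param gamma_p Pulsatility-enhancement gain (unitless).
#' @param a_ref Flow-acceleration scale (L/min per s).
#' @param c_art Saturation-limited oxygen content gain (mL O2 per L).
#' @param q_floor Minimum flow used in the residence-time term (L/min).
#' @param c_tau Shear gain (Pa per L/min).
#' @return A list of class `oracle_params`.
#' @export
oracle_params <- function(k_ref = 0.5, m_exp = 0.8, gamma_p = 1.5,
                          a_ref = 40, c_art = 60, q_floor = 0.05,
                          c_tau = 10) {
  vals <- c(k_ref, m_exp, gamma_p, a_ref, c_art, q_floor, c_tau)
  if (any(vals <= 0)) abort("All oracle parameters must be positive.")
  structure(list(k_ref = k_ref, m_exp = m_exp, gamma_p = gamma_p,
                 a_ref = a_ref, c_art = c_art, q_floor = q_floor,
                 c_tau = c_tau),
            class = "oracle_params")
}

#' Wall shear stress proxy
#'
#' Flow-proportional shear estimate `tau = c_tau * |q|` used by the oracle.
#'
#' @param q Flow (L/min); vectorized.
#' @param params An [oracle_params()] object.
#' @return Shear stress (Pa).
#' @export
wall_shear <- function(q, params = oracle_params()) {
  params$c_tau * abs(q)
}

#' Label a flow waveform with the pseudo-CFD oracle
#'
#' Maps one period of a feasible flow waveform to per-time-point oxygen
#' transfer and hemolysis labels plus cycle aggregates. At each time point,
#' with `u_t = max(|q_t|, q_floor)`:
#' \describe{
#'   \item{transfer coefficient}{`k_t = k_ref * u_t^m_exp * (1 + gamma_p *
#'     tanh(|dq_t| / a_ref))`}
#'   \item{per-pass saturation}{`f_t = 1 - exp(-k_t / u_t)` (residence time
#'     shrinks as flow grows)}
#'   \item{instantaneous transfer}{`otr_inst_t = c_art * f_t` (mL O2 / L)}
#'   \item{hemolysis increment}{`hem_inst_t = C * tau_t^b * dt^a` with
#'     `tau_t = c_tau * |q_t|`}
#' }
#' The cycle hemolysis index is the sum of increments; the cycle OTR is the
#' flow-weighted mean of `otr_inst` over samples with positive flow (reverse
#' flow delivers no oxygenated blood downstream but still contributes shear
#' damage).
#'
#' @param profile A feasible `flow_profile` (see [profile_is_feasible()]).
#' @param op An [oracle_params()] object.
#' @param hp A [hemolysis_params()] object.
#' @param limits A [pump_limits()] object used to validate feasibility.
#' @return A list of class `oracle_labels` with elements `labels` (tibble
#'   `time_s`, `flow_lpm`, `otr_inst`, `hem_inst`), `otr_episode` (mL O2 / L),
#'   `hem_episode` (%), and `params`.
#' @export
oracle_labels <- function(profile, op = oracle_params(),
                          hp = hemolysis_params(), limits = pump_limits()) {
  profile <- as_flow_profile(profile)
  if (!profile_is_feasible(profile, limits)) {
    abort("Profile violates pump limits; project it first.")
  }
  feats <- compute_features(profile)
  dt <- profile_dt(profile)
  q <- feats$q
  u <- pmax(abs(q), op$q_floor)
  k <- op$k_ref * u^op$m_exp * (1 + op$gamma_p * tanh(abs(feats$dq) / op$a_ref))
  f <- 1 - exp(-k / u)
  otr_inst <- op$c_art * f
  tau <- wall_shear(q, op)
  hem_inst <- hemolysis_fraction(tau, dt, hp)
  pos <- q > 0
  wsum <- sum(q[pos] * dt)
  if (wsum <= 0) {
    abort("No positive flow over the cycle; episode OTR is undefined.")
  }
  otr_episode <- sum(otr_inst[pos] * q[pos] * dt) / wsum
  structure(list(
    labels = tibble::tibble(time_s = feats$time_s, flow_lpm = q,
                            otr_inst = otr_inst, hem_inst = hem_inst),
    otr_episode = otr_episode,
    hem_episode = sum(hem_inst),
    params = list(oracle = unclass(op), hemolysis = unclass(hp))),
    class = "oracle_labels")
}

#' @export
print.oracle_labels <- function(x, ...) {
  cat(sprintf(
    "<oracle_labels: %d time points, cycle OTR = %.3f mL/L, cycle hemolysis = %.3g %%>\n",
    nrow(x$labels), x$otr_episode, x$hem_episode))
  invisible(x)
}

#' @export
tidy.oracle_labels <- function(x, ...) x$labels

#' @export
glance.oracle_labels <- function(x, ...) {
  tibble::tibble(otr_episode = x$otr_episode, hem_episode = x$hem_episode,
                 n_points = nrow(x$labels))
}

#' Write oracle labels to disk
#'
#' Emits the per-time-point labels as CSV and the episode aggregates plus the
#' full parameter set as a JSON sidecar.
#'
#' @param x An `oracle_labels` object.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_oracle_labels <- function(x, path) {
  readr::write_csv(x$labels, path)
  jsonlite::write_json(
    list(otr_episode = x$otr_episode, hem_episode = x$hem_episode,
         params = x$params),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Normalized index of hemolysis (NIH)
#'
#' Standard blood-pump hemolysis index: grams of plasma free hemoglobin
#' released per 100 L of blood pumped, corrected for hematocrit,
#' `NIH = dPFH * V * (100 - Hct)/100 * 100 / (Q * t)`.
#'
#' @param delta_pfh Rise in plasma free hemoglobin (g/L).
#' @param volume Circuit volume (L).
#' @param hct Hematocrit (%).
#' @param q_mean Mean flow (L/min).
#' @param duration Circulation time (min).
#' @return NIH (g per 100 L pumped).
#' @export
nih <- function(delta_pfh, volume, hct, q_mean, duration) {
  if (any(delta_pfh < 0)) abort("`delta_pfh` must be non-negative.")
  if (volume <= 0 || hct < 0 || hct > 100) abort("Invalid volume or hematocrit.")
  if (q_mean * duration <= 0) abort("`q_mean * duration` must be positive.")
  delta_pfh * volume * ((100 - hct) / 100) * 100 / (q_mean * duration)
}
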