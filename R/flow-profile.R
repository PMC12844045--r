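#' Uniform time grid for one pulsation period
#'
#' A periodic waveform is represented by samples on a uniform grid covering one
#' period `[0, period)`; the sample at `period` is identified with the one at 0.
#'
#' @param dt Seconds per sample. Must be positive.
#' @param n_steps Number of samples (at least 2). Exactly one of `n_steps` and
#'   `period` may be omitted; the other is derived via `period = dt * n_steps`.
#' @param period Period length in seconds.
#'
#' @return A list of class `time_grid` with fields `dt`, `n_steps`, `period`.
#' @export
#' @examples
#' time_grid(dt = 0.004, period = 0.8)
time_grid <- function(dt, n_steps = NULL, period = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number.")
  }
  if (is.null(n_steps) && is.null(period)) {
    abort("Supply at least one of `n_steps` and `period`.")
  }
  if (is.null(n_steps)) n_steps <- as.integer(round(period / dt))
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 2L) abort("`n_steps` must be at least 2.")
  if (is.null(period)) period <- dt * n_steps
  if (abs(dt * n_steps - period) > dt / 2) {
    abort("`dt * n_steps` must equal `period` (within half a sample).")
  }
  structure(list(dt = dt, n_steps = n_steps, period = period),
            class = "time_grid")
}

#' Blood-pump actuation limits
#'
#' Operating constraints of the pulsatile blood pump: absolute flow bounds, the
#' maximum permissible flow change per control interval, and the control
#' interval itself. Defaults are the pump's mechanical and safety limits:
#' flows clipped to −0.5 to 5.0 L/min and at most 0.4 L/min change per 4 ms
#' actuation step.
#'
#' @param q_min,q_max Flow bounds (L/min).
#' @param dq_max Maximum flow change per control step (L/min).
#' @param dt_ctrl Control interval (s).
#'
#' @return A list of class `pump_limits`.
#' @export
pump_limits <- function(q_min = -0.5, q_max = 5.0, dq_max = 0.4,
                        dt_ctrl = 0.004) {
  stopifnot(is.numeric(q_min), is.numeric(q_max), is.numeric(dq_max),
            is.numeric(dt_ctrl))
  if (!(q_min < q_max)) abort("`q_min` must be below `q_max`.")
  if (dq_max <= 0) abort("`dq_max` must be positive.")
  if (dt_ctrl <= 0) abort("`dt_ctrl` must be positive.")
  structure(list(q_min = q_min, q_max = q_max, dq_max = dq_max,
                 dt_ctrl = dt_ctrl),
            class = "pump_limits")
}

#' Construct a flow profile
#'
#' A flow profile is a tibble with columns `time_s` and `flow_lpm` holding one
#' period of a pulsatile waveform on a uniform time grid, plus attributes for
#' the period and whether the profile has been projected onto the pump
#' constraint set.
#'
#' @param time_s Sample times (s), uniformly spaced, starting at 0.
#' @param flow_lpm Flow values (L/min), same length as `time_s`.
#' @param period Period (s); defaults to `dt * length(time_s)`.
#' @param projected Logical flag: does the profile satisfy the pump limits?
#' @param family Optional waveform family tag.
#'
#' @return A tibble of class `flow_profile`.
#' @export
#' @examples
#' flow_profile(seq(0, 0.796, by = 0.004), rep(0.9, 200))
flow_profile <- function(time_s, flow_lpm, period = NULL, projected = FALSE,
                         family = NULL) {
  if (length(time_s) != length(flow_lpm)) {
    abort("`time_s` and `flow_lpm` must have the same length.")
  }
  if (length(time_s) < 2L) abort("A profile needs at least 2 samples.")
  if (!all(is.finite(flow_lpm))) abort("All flow values must be finite.")
  dts <- diff(time_s)
  if (any(dts <= 0) || diff(range(dts)) > 1e-9 * dts[1]) {
    abort("`time_s` must be uniformly increasing.")
  }
  dt <- dts[1]
  period <- period %||% (dt * length(time_s))
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        flow_lpm = as.numeric(flow_lpm))
  structure(out,
            class = c("flow_profile", class(out)),
            period = period, projected = isTRUE(projected), family = family)
}

#' Coerce a data frame to a flow profile
#'
#' @param x A data frame with columns `time_s` and `flow_lpm`.
#' @param ... Passed to [flow_profile()].
#' @return A `flow_profile` tibble.
#' @export
as_flow_profile <- function(x, ...) {
  if (inherits(x, "flow_profile")) return(x)
  if (!all(c("time_s", "flow_lpm") %in% names(x))) {
    abort("Need columns `time_s` and `flow_lpm`.")
  }
  flow_profile(x$time_s, x$flow_lpm, ...)
}

profile_grid <- function(profile) {
  dt <- profile$time_s[2] - profile$time_s[1]
  time_grid(dt = dt, n_steps = nrow(profile),
            period = attr(profile, "period") %||% (dt * nrow(profile)))
}

profile_dt <- function(profile) profile$time_s[2] - profile$time_s[1]

is_projected <- function(profile) isTRUE(attr(profile, "projected"))

#' @export
print.flow_profile <- function(x, ...) {
  g <- profile_grid(x)
  cat(sprintf(
    "<flow_profile: %d samples, dt = %g s, period = %g s, mean = %.4g L/min%s>\n",
    g$n_steps, g$dt, g$period, mean(x$flow_lpm),
    if (is_projected(x)) ", projected" else ""))
  NextMethod()
}

#' Read / write waveform CSV files
#'
#' The on-disk exchange format is a two-column CSV `time_s,flow_lpm` (header
#' required) holding one period per file.
#'
#' @param path File path.
#' @return `read_waveform_csv()` returns a `flow_profile`;
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), flow_lpm = readr::col_double()))
  as_flow_profile(df)
}

#' @rdname read_waveform_csv
#' @param profile A `flow_profile`.
#' @export
write_waveform_csv <- function(profile, path) {
  readr::write_csv(tibble::tibble(time_s = profile$time_s,
                                  flow_lpm = profile$flow_lpm), path)
  invisible(path)
}

#' @export
autoplot.flow_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$flow_lpm)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(x = "Time (s)", y = "Flow (L/min)")
}

#' @importFrom ggplot2 .data
NULL
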