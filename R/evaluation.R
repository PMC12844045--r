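#' Waveform fidelity metrics
#'
#' Pointwise agreement between a target waveform and an actually realized
#' one: RMSE, MAE, Pearson correlation, coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (both correlation and R-squared are reported
#' explicitly since the two are often conflated), and peak-timing delays from
#' nearest-peak pairing within half a period.
#'
#' @param target,actual `flow_profile`s on the same grid.
#' @return A one-row tibble of class `fidelity_report`: `rmse`, `mae`,
#'   `r_squared`, `pearson_r`, `mean_peak_delay_ms`, `max_peak_delay_ms`,
#'   `correlation_defined`. For constant series the correlation is undefined:
#'   `correlation_defined` is `FALSE` and the correlation columns are `NA`
#'   (flagged, not silently numeric).
#' @export
fidelity_metrics <- function(target, actual) {
  target <- as_flow_profile(target)
  actual <- as_flow_profile(actual)
  if (nrow(target) != nrow(actual) ||
      max(abs(target$time_s - actual$time_s)) > 1e-9) {
    abort("Profiles must share the same time grid.")
  }
  x <- target$flow_lpm
  y <- actual$flow_lpm
  rmse <- sqrt(mean((y - x)^2))
  mae <- mean(abs(y - x))
  const <- sd(x) < 1e-12 || sd(y) < 1e-12
  if (const) {
    r <- NA_real_
    r2 <- NA_real_
  } else {
    r <- stats::cor(x, y)
    r2 <- 1 - sum((y - x)^2) / sum((x - mean(x))^2)
  }
  delays <- peak_delays(target, actual)
  out <- tibble::tibble(rmse = rmse, mae = mae, r_squared = r2, pearson_r = r,
                        mean_peak_delay_ms = delays$mean_ms,
                        max_peak_delay_ms = delays$max_ms,
                        correlation_defined = !const)
  class(out) <- c("fidelity_report", class(out))
  out
}

local_peaks <- function(q) {
  n <- length(q)
  if (n < 3) return(integer(0))
  which(q[2:(n - 1)] > q[1:(n - 2)] & q[2:(n - 1)] >= q[3:n]) + 1L
}

peak_delays <- function(target, actual) {
  pt <- local_peaks(target$flow_lpm)
  pa <- local_peaks(actual$flow_lpm)
  if (length(pt) == 0 || length(pa) == 0) {
    return(list(mean_ms = NA_real_, max_ms = NA_real_))
  }
  half <- (attr(target, "period") %||%
             (profile_dt(target) * nrow(target))) / 2
  d <- purrr::map_dbl(target$time_s[pt], function(tt) {
    dd <- min(abs(actual$time_s[pa] - tt))
    if (dd <= half) dd else NA_real_
  })
  d <- d[!is.na(d)]
  if (length(d) == 0) return(list(mean_ms = NA_real_, max_ms = NA_real_))
  list(mean_ms = mean(d) * 1000, max_ms = max(d) * 1000)
}

#' Percent improvement of a candidate over a reference
#'
#' `100 * (candidate - reference) / reference`, reported to two decimals.
#'
#' @param reference,candidate Scalar values; `reference` must be non-zero.
#' @return Percent improvement (two decimals).
#' @export
#' @examples
#' percent_improvement(19.28, 23.26)  # 20.64
percent_improvement <- function(reference, candidate) {
  if (any(reference == 0)) abort("`reference` must be non-zero.")
  round(100 * (candidate - reference) / reference, 2)
}

#' Independent two-sample t-test
#'
#' Classic Student's test with pooled variance by default (Welch's unequal
#' variance version behind `var_equal = FALSE`), two-sided.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `method`.
#' @export
independent_t_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_a = mean(group_a),
                 mean_b = mean(group_b), method = ht$method)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n-1 denominator) divided by `sqrt(n)`.
#'
#' @param values Numeric vector of length at least 2.
#' @return SEM.
#' @export
sem <- function(values) {
  if (length(values) < 2) abort("Need at least 2 values.")
  sd(values) / sqrt(length(values))
}

#' Simulate a blood-gas sampling experiment for a flow profile
#'
#' Synthetic stand-in for pre/post-oxygenator blood sampling: the outlet
#' oxygen content equals the inlet content plus the oracle's cycle oxygen
#' transfer plus Gaussian measurement noise, and the outlet gas values are
#' back-allocated through the content formula — saturation filled first up to
#' 100%, the remainder assigned to the dissolved term. With zero noise the
#' recovered transfer rate reproduces the oracle value exactly.
#'
#' @param profile A feasible `flow_profile`.
#' @param op,hp Oracle and hemolysis parameters.
#' @param inlet Inlet [blood_gas()] (one row).
#' @param noise_sd Measurement noise on outlet content (mL O2 / L).
#' @param n_reps Number of replicates (the bench protocol uses 3).
#' @param seed Seed for the noise draws.
#' @param po2_ceiling Maximum physically plausible outlet pO2 (mmHg); content
#'   beyond the saturated cap plus this dissolved ceiling is an error.
#' @return A tibble with one row per replicate: `rep`, `hb_pre`, `so2_pre`,
#'   `po2_pre`, `hb_post`, `so2_post`, `po2_post`, `otr_measured`, plus
#'   attribute `otr_episode` (the oracle value).
#' @export
simulate_bloodgas_experiment <- function(profile, op = oracle_params(),
                                         hp = hemolysis_params(),
                                         inlet = blood_gas(10, 65, 40),
                                         noise_sd = 0.5, n_reps = 3,
                                         seed = 1L, po2_ceiling = 700) {
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  if (nrow(inlet) != 1) abort("`inlet` must be a single blood-gas row.")
  otr <- oracle_labels(profile, op, hp)$otr_episode
  c_pre <- oxygen_content(inlet)
  noise <- withr::with_seed(seed, rnorm(n_reps, 0, noise_sd))
  rows <- purrr::map(seq_len(n_reps), function(r) {
    c_post <- c_pre + otr + noise[r]
    hb <- inlet$hb
    cap <- 13.4 * hb  # content at full saturation, dissolved term excluded
    if (c_post <= cap + 0.0314 * inlet$po2) {
      # keep the inlet pO2 and put everything into saturation
      so2 <- (c_post - 0.0314 * inlet$po2) / (13.4 * hb) * 100
      po2 <- inlet$po2
    } else {
      so2 <- 100
      po2 <- (c_post - cap) / 0.0314
      if (po2 > po2_ceiling) {
        abort("Outlet content exceeds the physical cap at so2 = 100%.")
      }
    }
    tibble::tibble(rep = r, hb_pre = hb, so2_pre = inlet$so2,
                   po2_pre = inlet$po2, hb_post = hb, so2_post = so2,
                   po2_post = po2,
                   otr_measured = o2_transfer_rate(
                     inlet, blood_gas(hb, so2, po2)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "otr_episode") <- otr
  out
}

#' Compare two flow profiles on oxygen transfer
#'
#' Runs the synthetic blood-gas experiment on both profiles and assembles the
#' group statistics: per-group mean and SEM, independent t-test, and percent
#' improvement of the candidate over the reference.
#'
#' @param reference,candidate Feasible `flow_profile`s (e.g. the half-sine
#'   baseline and an optimized profile).
#' @param op,hp Oracle and hemolysis parameters.
#' @param n_reps Replicates per group.
#' @param noise_sd Measurement noise (mL O2 / L).
#' @param seed Seed (split between groups).
#' @return A list of class `comparison_report`: `groups` tibble
#'   (mean OTR, SEM, cycle hemolysis per profile), `t_test`,
#'   `percent_improvement` (on the noise-free oracle values).
#' @export
compare_profiles <- function(reference, candidate, op = oracle_params(),
                             hp = hemolysis_params(), n_reps = 3,
                             noise_sd = 0.5, seed = 1L) {
  ref <- simulate_bloodgas_experiment(reference, op, hp, n_reps = n_reps,
                                      noise_sd = noise_sd, seed = seed)
  cand <- simulate_bloodgas_experiment(candidate, op, hp, n_reps = n_reps,
                                       noise_sd = noise_sd, seed = seed + 1L)
  groups <- tibble::tibble(
    group = c("reference", "candidate"),
    otr_oracle = c(attr(ref, "otr_episode"), attr(cand, "otr_episode")),
    otr_mean = c(mean(ref$otr_measured), mean(cand$otr_measured)),
    otr_sem = c(sem(ref$otr_measured), sem(cand$otr_measured)),
    hem_episode = c(oracle_labels(reference, op, hp)$hem_episode,
                    oracle_labels(candidate, op, hp)$hem_episode))
  structure(list(
    groups = groups,
    t_test = independent_t_test(cand$otr_measured, ref$otr_measured),
    percent_improvement = percent_improvement(groups$otr_oracle[1],
                                              groups$otr_oracle[2])),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$groups)
  cat(sprintf("candidate vs reference: %+.2f%% (t = %.3f, p = %.4g)\n",
              x$percent_improvement, x$t_test$t, x$t_test$p_value))
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) x$groups

#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(percent_improvement = x$percent_improvement,
                 t = x$t_test$t, p_value = x$t_test$p_value)
}
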