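#' Default pipeline configuration
#'
#' A single nested list with the blocks `waveforms`, `oracle`, `surrogate`,
#' `env`, `agent`, and `eval`, mirroring the YAML layout accepted by
#' [run_pipeline()]. `small = TRUE` shrinks the corpus and the networks for
#' quick smoke runs.
#'
#' @param small Use reduced sizes.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A nested configuration list.
#' @export
pulseopt_config <- function(small = FALSE, seed = 42L) {
  list(
    waveforms = list(n_profiles = if (small) 60L else 2000L, dt = 0.01,
                     period = 0.8, target_mean_range = c(0.6, 1.3),
                     seed = seed),
    oracle = c(unclass(oracle_params()), unclass(hemolysis_params())),
    surrogate = list(
      otr_hidden = if (small) c(256, 128, 32) else c(1024, 512, 64),
      hem_hidden = c(64, 16),
      otr_max_epochs = if (small) 6L else 18L,
      hem_max_epochs = if (small) 60L else 400L,
      seed = seed),
    env = list(dt_ctrl = 0.004, n_steps = 200L, q_tar = 0.9,
               history_n = 5L, q_init = 0, backend = "oracle"),
    agent = list(total_steps = if (small) 2000L else 14000L,
                 scale = 1 / 100, seed = seed),
    eval = list(n_reps = 3L, noise_sd = 0.5, seed = seed))
}

config_oracle <- function(cfg) {
  oc <- cfg$oracle
  list(
    op = oracle_params(k_ref = oc$k_ref, m_exp = oc$m_exp,
                       gamma_p = oc$gamma_p, a_ref = oc$a_ref,
                       c_art = oc$c_art, q_floor = oc$q_floor,
                       c_tau = oc$c_tau),
    hp = hemolysis_params(c_coef = oc$c_coef, a_exp = oc$a_exp,
                          b_exp = oc$b_exp))
}

validate_config <- function(cfg) {
  needed <- c("waveforms", "oracle", "surrogate", "env", "agent", "eval")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    abort(sprintf("Configuration is missing required block(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [pulseopt_config()];
#' all six blocks must exist in the merged result.
#'
#' @param path YAML file path.
#' @param small Base defaults on the reduced configuration.
#' @return A validated configuration list.
#' @export
read_pulseopt_config <- function(path, small = FALSE) {
  user <- yaml::read_yaml(path)
  base <- pulseopt_config(small = small)
  for (block in names(user)) {
    base[[block]] <- modifyList(base[[block]] %||% list(), user[[block]])
  }
  validate_config(base)
}

#' Run the full optimization pipeline
#'
#' Executes the stages end to end: generate the waveform corpus, label it
#' with the oracle, train the two surrogates, train the recurrent PPO agent
#' under the constrained environment, extract the optimized profile, and
#' compare it against the half-sine baseline at matched mean flow. All
#' randomness derives from the configured seeds, so a rerun with the same
#' configuration reproduces every number.
#'
#' @param config A configuration list (see [pulseopt_config()]) or a YAML
#'   path.
#' @param out_dir Optional output directory for reports (CSV/JSON).
#' @param verbose Print stage progress.
#' @return A list of class `pipeline_result`: `dataset`, `surrogates`,
#'   `surrogate_metrics` (threshold-accuracy table), `agent`,
#'   `optimized_profile`, `hspp`, `comparison`.
#' @export
run_pipeline <- function(config = pulseopt_config(small = TRUE),
                         out_dir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_pulseopt_config(config)
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  orc <- config_oracle(config)

  say("[gen-data] %d profiles", config$waveforms$n_profiles)
  specs <- sample_waveform_specs(
    n_profiles = config$waveforms$n_profiles, seed = config$waveforms$seed,
    target_mean_range = config$waveforms$target_mean_range,
    period = config$waveforms$period)
  ds <- build_dataset(specs, orc$op, orc$hp, dt = config$waveforms$dt)
  ds <- split_dataset(ds, seed = config$waveforms$seed)

  say("[train-surrogate] otr %s / hem %s",
      paste(config$surrogate$otr_hidden, collapse = "-"),
      paste(config$surrogate$hem_hidden, collapse = "-"))
  scfg <- surrogate_config(
    otr_hidden = config$surrogate$otr_hidden,
    hem_hidden = config$surrogate$hem_hidden,
    otr_max_epochs = config$surrogate$otr_max_epochs,
    hem_max_epochs = config$surrogate$hem_max_epochs,
    seed = config$surrogate$seed)
  sur_otr <- train_surrogate(ds, scfg, "otr")
  sur_hem <- train_surrogate(ds, scfg, "hem")
  metrics <- dplyr::bind_rows(
    dplyr::mutate(surrogate_test_accuracy(sur_otr, ds), model = "otr"),
    dplyr::mutate(surrogate_test_accuracy(sur_hem, ds), model = "hem"))
  metrics <- tidyr::pivot_wider(metrics, names_from = "threshold_pct",
                                values_from = "accuracy",
                                names_prefix = "acc_")

  say("[train-agent] %d env steps", config$agent$total_steps)
  env_cfg <- env_config(
    dt_ctrl = config$env$dt_ctrl, n_steps = config$env$n_steps,
    q_tar = config$env$q_tar, history_n = config$env$history_n,
    q_init = config$env$q_init, backend = config$env$backend,
    oracle = orc$op, hemolysis = orc$hp,
    surrogates = if (config$env$backend == "surrogate") {
      list(otr = sur_otr, hem = sur_hem)
    })
  schedule <- train_schedule(total_steps = config$agent$total_steps,
                             scale = config$agent$scale,
                             seed = config$agent$seed)
  agent <- train_agent(env_cfg, schedule, verbose = FALSE)

  say("[evaluate] extracting optimized profile, comparing to HSPP")
  opt <- extract_optimized_profile(agent)
  hspp <- generate_hspp(period = env_cfg$period, target_mean = env_cfg$q_tar,
                        dt = env_cfg$dt_ctrl, limits = env_cfg$limits)
  comparison <- compare_profiles(hspp, opt, orc$op, orc$hp,
                                 n_reps = config$eval$n_reps,
                                 noise_sd = config$eval$noise_sd,
                                 seed = config$eval$seed)

  result <- structure(list(dataset = ds,
                           surrogates = list(otr = sur_otr, hem = sur_hem),
                           surrogate_metrics = metrics, agent = agent,
                           optimized_profile = opt, hspp = hspp,
                           comparison = comparison, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$surrogate_metrics)
  print(x$comparison)
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$surrogate_metrics,
                   file.path(out_dir, "surrogate_metrics.csv"))
  readr::write_csv(result$agent$history,
                   file.path(out_dir, "training_log.csv"))
  write_waveform_csv(result$optimized_profile,
                     file.path(out_dir, "drl_opp.csv"))
  write_waveform_csv(result$hspp, file.path(out_dir, "hspp.csv"))
  jsonlite::write_json(
    list(groups = result$comparison$groups,
         t_test = result$comparison$t_test,
         percent_improvement = result$comparison$percent_improvement,
         seeds = list(waveforms = result$config$waveforms$seed,
                      surrogate = result$config$surrogate$seed,
                      agent = result$config$agent$seed,
                      eval = result$config$eval$seed)),
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}
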