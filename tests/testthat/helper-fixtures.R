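# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small labelled corpus for surrogate mechanics tests
small_dataset <- function() {
  cached("small_ds", function() {
    specs <- sample_waveform_specs(n_profiles = 60, seed = 7)
    split_dataset(build_dataset(specs), seed = 7)
  })
}

small_surrogate_cfg <- function(...) {
  defaults <- list(otr_hidden = c(64, 32), hem_hidden = c(32, 8),
                   otr_max_epochs = 40, hem_max_epochs = 80,
                   otr_patience = 10, hem_patience = 20)
  do.call(surrogate_config, utils::modifyList(defaults, list(...)))
}

constant_profile <- function(value = 0.9, n = 200, dt = 0.004) {
  flow_profile((seq_len(n) - 1) * dt, rep(value, n), projected = TRUE)
}

# independent GAE oracle: direct double sum over TD errors
gae_bruteforce <- function(rewards, values, gamma, lam, bootstrap = 0) {
  n <- length(rewards)
  v_next <- c(values[-1], bootstrap)
  nonterm <- c(rep(1, n - 1), 0)
  delta <- rewards + gamma * v_next * nonterm - values
  adv <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (l in 0:(n - t)) acc <- acc + (gamma * lam)^l * delta[t + l]
    adv[t] <- acc
  }
  adv
}
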