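Package: pulseopt
Title: Reinforcement-Learning Optimization of Pulsatile Flow Waveforms for
    Membrane Oxygenators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering pulsatile blood-flow waveforms that maximize
    membrane-oxygenator oxygen transfer while penalizing hemolysis. Provides
    parametric waveform generators (half-sine pulse, sine, pulmonary-artery-like,
    composite-Gaussian and Gaussian-exponential families) under blood-pump
    actuation constraints, an analytic pseudo-CFD oracle producing per-time-point
    oxygen-transfer and hemolysis labels, feed-forward neural surrogates of the
    oracle trained with AdamW and early stopping, a constrained episodic control
    environment with a multi-objective reward, a recurrent (LSTM) proximal policy
    optimization agent, and evaluation utilities (waveform fidelity metrics,
    blood-gas arithmetic, normalized index of hemolysis, and group statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
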