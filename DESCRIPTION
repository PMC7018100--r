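Package: comdyn
Title: Neural Circuit Dynamics of Decision Uncertainty and Changes-of-Mind
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a reduced cortical circuit model of perceptual
    decision making in which a dedicated uncertainty-monitoring neural
    population feeds excitation back to two competing sensorimotor
    populations, occasionally destabilising the winner-take-all choice
    attractor and producing a change-of-mind in the downstream hand
    (motor) populations. Provides a stochastic Euler-Maruyama trial
    simulator with per-trial seeding, deterministic fixed-point and
    saddle-node bifurcation analysis of the two-variable sensorimotor
    subsystem, tidy summary statistics of simulated experiments
    (psychometric curves, change-of-mind probabilities by coherence,
    response-time and uncertainty tertiles), and mouse-tracking
    trajectory tools: a change-of-mind detector and response-onset
    extractor implementing pixel-threshold labelling rules, plus a
    synthetic cursor-trajectory generator for validating them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    withr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
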