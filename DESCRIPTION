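Package: sixmass
Title: Six-Mass Vocal-Fold Model Simulation and Neural Inverse Parameter Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of a dimensionality-reduced one-dimensional
    six-mass lumped-element model of vocal-fold oscillation (two sides, three
    longitudinal sections, two vertical masses each, driven by Bernoulli
    subglottal pressure), synthetic trajectory dataset generation with
    log-uniform parameter scaling and gamma-marginal/normal-copula rest-position
    sampling, and a convolutional-recurrent surrogate network that inverts
    observed vocal-fold edge trajectories to the 14 biomechanical scaling
    parameters (masses, anchor stiffnesses, subglottal pressure, collision
    proportionality). Includes observable-space evaluation (fundamental
    frequency, amplitude, MAE/MAPE) and statistical-guess baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    fitdistrplus,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
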