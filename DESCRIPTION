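Package: mcrelease
Title: Monte Carlo Simulation and Inference of Drug Release Kinetics
Version: 0.1.0
Authors@R: person("mcrelease", "developers", role = c("aut", "cre"),
    email = "maintainers@mcrelease.invalid")
Description: Lattice Monte Carlo simulation of drug release from a
    cylindrical solid dosage form with pluggable Monte Carlo Micro-Step
    (MCS) time models (Fickian diffusion, stochastic polymer erosion, and
    a hybrid deterministic/stochastic template), release-curve fitting
    with the Weibull, linear and Higuchi dissolution models, ensemble
    statistics over replicate simulations, and genetic-algorithm
    inference of hybrid MCS parameters from an observed release curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
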