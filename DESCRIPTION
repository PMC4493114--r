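Package: trendcp
Title: Spatial Hierarchical Bayesian Annual Indices and Change-Point
    Detection for Survey Count Trends
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-stage hierarchical Bayesian pipeline for detecting
    shared changes in population trends from breeding-bird-survey-style
    route count data.  Stage one fits an overdispersed Poisson annual-index
    model with observer effects and an intrinsic conditional autoregressive
    (CAR) spatial structure on stratum-by-year effects, producing
    bias-corrected annual abundance indices with log-scale uncertainties.
    Stage two treats those indices as data and fits a piecewise-linear
    regression-spline change-point model by reversible-jump MCMC,
    separating group-level from species-specific changes in trend, with
    deviance information criterion (DIC) comparison of competing group
    structures and posterior-to-prior odds-ratio summaries of change-point
    timing, direction, and magnitude.  Includes a synthetic-data generator
    with the exact generative structure both stages assume, and an exact
    enumeration oracle for validating the reversible-jump sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    coda
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
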