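Package: stochwc
Title: Criticality Analysis of the Stochastic Wilson-Cowan Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying critical behaviour in the stochastic
    Wilson-Cowan model of coupled excitatory and inhibitory neural
    populations. Provides the deterministic fixed-point and stability
    analysis, the linear-noise approximation (stationary covariance by the
    Lyapunov equation, analytic time-correlation functions, firing-rate
    statistics), exact Gillespie simulation of the underlying Markov jump
    process and Euler-Maruyama integration of the equivalent Langevin
    equations, neuronal-avalanche detection (time-binned and threshold
    based) with discrete and continuous power-law maximum-likelihood
    estimation, size-duration scaling and shape collapse, empirical
    autocorrelation with correlation-time extraction, and ground-truth
    synthetic fixtures (critical branching process, Ornstein-Uhlenbeck,
    power-law samplers, small-N master-equation oracle) for estimator
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
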