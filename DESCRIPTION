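Package: dyadnorm
Title: Emergence of Perceptual Norms Through Dyadic Interaction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how perceptual norms
    emerge through dyadic interaction in magnitude-estimation tasks.
    Provides generators for virtual dot-estimation experiments (laboratory
    pair/individual, scanner, and online 2x2 designs), maximum-likelihood
    fitting of linear and log-linear psychophysical weights, reciprocating
    (Sherif-type) and unresponsive (Asch-type) computer-partner agents, a
    hierarchical Bayesian local-level state-space model yielding a
    per-participant stability index for the estimation weight, and a
    time-varying-coefficient decomposition of social influence during
    interaction with WAIC model comparison and posterior predictive checks.
    All samplers are implemented natively (forward-filtering
    backward-sampling Gibbs with Metropolis steps) in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
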