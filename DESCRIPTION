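Package: ringnav
Title: Hypothesis-Based Localization on a Circular Track with Ambiguous Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of spatial reasoning with perceptually
    identical landmarks on a circular track. Provides generators for noisy
    velocity trajectories and landmark encounters, Bayesian baseline agents
    (path integration with landmark correction, basic and enhanced particle
    filters, an exact grid-Bayes oracle), a trainable recurrent rate network
    that localizes from velocity and map inputs, population-activity analyses
    (state-space PCA, correlation dimension, tuning-correlation structure,
    hypothesis disambiguation), a synthetic Poisson spike-session generator
    emulating retrosplenial population recordings, and the associated
    population statistics (histogram entropies, spatial maps, phase decoding,
    correlation-of-correlations, cross-population rate prediction, group
    distance tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
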