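Package: autorep
Title: Stochastic Dynamics and Single-Cell Trajectory Analysis of a
    Self-Repressing Gene Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie SSA) and truncated
    chemical-master-equation solution of an inducer-coupled negative
    auto-regulation (self-repressing) gene circuit, in which the speed of
    operator binding/unbinding is tuned by an inducer that sequesters the
    repressor. Slow (non-adiabatic) operator kinetics produce bimodal
    steady-state expression and two interconverting cell fates. The package
    also provides the matching single-cell analysis toolchain: two-state
    Gaussian-emission hidden Markov model fitting of log-fluorescence
    trajectories by Baum-Welch, Viterbi segmentation, residence-time
    estimation, expression-noise statistics (Fano factor, CV, inhibition
    curves), mode detection, and a synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
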