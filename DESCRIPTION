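Package: clonetrace
Title: Barcode Lineage Tracing and Colonization-Bottleneck Inference for
    Gut Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing neutral-barcode (wild-type isogenic tagged
    strain) colonization experiments in gnotobiotic animals. Provides
    maximum-likelihood and variance-based estimators of the per-cell
    colonization probability from barcode loss patterns, with
    profile-likelihood confidence intervals and spike-in design helpers; a
    lag/net-growth/clearance competition model for predicting competitive
    indices and competition-conditional colonization probabilities; growth
    curve fitting for censored CFU time courses; cecal turnover arithmetic
    from gut physiology measurements; and a forward stochastic simulator
    (Poisson inoculum, Bernoulli early killing, hybrid Gillespie birth-death
    growth against a deterministic bulk, dilution-plating and qPCR
    measurement noise) that doubles as a synthetic-data generator for
    validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
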