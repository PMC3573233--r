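Package: bgdcm
Title: Dynamic Causal Modelling of Beta Oscillations in the
    Cortico-Basal-Ganglia-Thalamocortical Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Neural-mass modelling and Bayesian system identification of
    beta-band (13-35 Hz) interactions in the motor
    cortico-basal-ganglia-thalamocortical circuit.  Provides a
    six-source neural-mass generative model of steady-state
    cross-spectral densities, vector-autoregressive spectral feature
    extraction for multichannel LFP/EEG recordings, variational Laplace
    inversion contrasting two conditions through extrinsic-gain
    modulation, fixed-effects Bayesian model comparison across candidate
    architectures, group-level significance criteria, and contribution
    (sensitivity) and in-silico lesion analyses.  A synthetic-data
    generator produces ground-truth cohorts so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
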