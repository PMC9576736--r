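Package: quantalglu
Title: Optical Quantal Analysis of Single-Synapse Glutamate Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for optical quantal analysis of fluorescent glutamate
    sensor (iGluSnFR) recordings from single presynaptic boutons. The
    package synthesizes trial-resolved spiral-scan sessions with known
    ground truth, extracts quality-controlled per-trial response
    amplitudes (dynamic region of interest, bleach correction, template
    fitting, 2-sigma classification), fits a binomial vesicular release
    model with saturation-spaced, shot-noise-broadened Gaussian mixtures
    jointly across two calcium conditions to recover the quantal
    parameters N, p_ves and q, localizes release sites by 2D Gaussian
    fitting with 95% confinement ellipses, and validates the sensor
    saturation model with a reduced Brownian-dynamics simulation of
    glutamate diffusion in the synaptic cleft.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
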