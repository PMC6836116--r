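Package: latmask
Title: Lateral Masking Contrast-Sensitivity Analysis with Probit Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for two-alternative forced-choice
    (2AFC) contrast-detection experiments with collinear lateral masking.
    Generates synthetic observer populations and trial-level data under a
    probit psychometric model with per-observer random intercepts and
    contrast slopes, fits binomial probit-link mixed-effects models by
    marginal maximum likelihood with adaptive Gauss-Hermite quadrature,
    derives 75 percent-correct contrast thresholds with parametric-bootstrap
    uncertainty, and computes baseline-normalized facilitation/inhibition
    profiles across flanker distances. Includes Gabor stimulus rendering
    for design validation and documentation figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
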