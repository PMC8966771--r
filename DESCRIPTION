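Package: canopygp
Title: Genomic Prediction of Canopy Green-Fraction Growth Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the growth trajectories of untested crop
    genotypes from UAV-derived canopy cover time series. A five-parameter
    leaf-area-index dynamics model (logistic growth plus exponential
    senescence on a growing-degree-day scale) is fitted to plot-level green
    fraction series in two stages; genotypic values of per-date green
    fraction and of the curve parameters are extracted with mixed models;
    single-trait G-BLUP and a multi-trait Gibbs sampler with a Kronecker
    genetic covariance propagate genomic information; and six prediction
    schemes (GP, TGP, MGP, TMGP, TGPG, TMGPG), including approximate
    Bayesian computation refinement from early-season observations, are
    evaluated under three cross-validation designs. A synthetic-data
    generator emulating a multi-environment soybean field trial makes the
    whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
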