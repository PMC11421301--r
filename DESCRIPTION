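Package: dcsm
Title: Dual Change Score Models for Longitudinal Twin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Univariate and bivariate dual change score models (DCSMs) for
    longitudinal aging traits observed on a 2-year age grid, with random
    intercepts and slopes at both the individual and the twin-pair level.
    Implements full-information maximum likelihood (FIML) estimation under
    arbitrary missingness, proportional (self-feedback) and cross-trait
    coupling dynamics, likelihood-ratio model selection ladders, a
    synthetic-data generator emulating the design of the Swedish
    Adoption/Twin Study of Aging (SATSA), frailty-index computation from
    deficit items, and reporting utilities (model-implied trajectories,
    vector-field plots with 95% data ellipses, baseline correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
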