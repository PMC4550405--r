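Package: svcmap
Title: Multilevel Ecological Regression with Spatially Varying City
    Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian ecological-regression modelling of small-area
    (census-tract) health outcomes across sets of non-adjacent cities.
    Implements three nested hierarchical Poisson models -- independent city
    coefficients, exchangeable random coefficients, and geostatistical
    spatially correlated coefficients with exponential distance-decay
    covariance -- with BYM-type intrinsic CAR and heterogeneity random
    effects at tract level.  Inference is by Metropolis-within-Gibbs MCMC
    with Brooks-Gelman-Rubin and effective-sample-size diagnostics and DIC
    model comparison.  City-level relative-risk coefficients can be kriged
    onto continuous prediction grids, giving posterior mean, standard
    deviation and exceedance-probability surfaces.  Includes indirect
    standardization of expected counts, GeoBUGS adjacency interoperability,
    and a synthetic-data generator mirroring the geostatistical model for
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    geosphere
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
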