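Package: leafoptics
Title: Leaf Radiative-Transfer Simulation, Inversion and Surrogate Modelling of
    Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of leaf directional-hemispherical reflectance and
    transmittance with a generalized plate model of the PROSPECT-D family
    (structure parameter plus chlorophyll, carotenoid, anthocyanin, water and dry
    matter contents), reflectance-only inversion by bounded optimization, and the
    inversion-forward regeneration cycle with per-wavelength error statistics.
    Includes cross-dataset transferability analysis of trait models by partial
    least squares regression, one-at-a-time sensitivity profiles, a feed-forward
    neural-network surrogate for inversion with integrated-gradients wavelength
    attribution, per-wavelength broad-sense heritability from multi-environment
    trials, and a synthetic-data generator (optical constants, trait population
    archetypes, band-localized measurement noise, genotype trials) that makes the
    whole framework testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    mixOmics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
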