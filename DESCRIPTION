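Package: rearnet
Title: Host Use and Interaction Networks from Drosophilid Rearing Records
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing plant-drosophilid rearing surveys: reading
    and validating rearing records (weighed sample units and per-species
    emergence counts), building fly-by-host interaction matrices,
    sample-based rarefaction, rank-abundance structure, host-use density and
    emergence success rates, specialist/generalist niche-breadth
    classification, and an origin-class matrix-occupancy analysis
    (chi-square goodness of fit with exact binomial post hoc tests).
    Includes a generative simulator of rearing surveys (log-series fly
    abundances, lognormal sample masses, origin-structured fly-host
    compatibility, negative-binomial emergence counts) for calibration and
    parameter-recovery experiments, and a packaged summary of a published
    two-period survey at a fruit and vegetable distribution center in
    central Brazil.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
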