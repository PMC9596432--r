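Package: piliagg
Title: Simulation and Image-Based Quantification of Adhesin-Driven
    Bacterial Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rigid-body Langevin simulations of bacterial cells decorated
    with adhesive surface sites (a coarse-grained model of type-IV-pilus
    mediated cell-cell adhesion), comparing localized (polar patch) against
    dispersed (uniform) adhesin placement. Simulated configurations and
    phase-contrast-like micrographs are reduced to binary occupancy images,
    and the typical multicellular aggregate size is quantified as twice the
    correlation length of the radially averaged spatial autocorrelation of
    the occupancy field, fitted with an offset exponential. Includes a
    synthetic-data module (correlated binary fields, micrograph fixtures
    with ground-truth masks) and an end-to-end strain-comparison pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
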