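Package: dtfm
Title: Digital Traction Force Microscopy for Cell Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation-backed digital traction force microscopy (TFM) for
    multicellular colonies. Generates random, curvature-controlled colony
    geometries, solves a contractile elastic-monolayer-on-elastic-foundation
    continuum model for ground-truth traction maps, assembles normalized and
    augmented training corpora, and trains a conditional adversarial
    image-to-image network (U-Net generator, patch discriminator) that paints
    traction force maps from cell geometry and substrate properties. An
    inverse U-Net recovers hidden substrate stiffness fields and the
    contractility-stiffness relation from traction maps. Includes durotaxis
    asymmetry analysis, pixelwise error metrics, and a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
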