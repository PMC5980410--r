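Package: canopychange
Title: Individual-Tree Growth, Loss, and Biomass Change from Multitemporal
    Airborne Lidar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for individual-tree change detection between two airborne
    lidar acquisitions over the same forest. Builds digital elevation and
    smoothed canopy height models from point clouds, delineates tree crowns
    with an iterative multistory watershed, co-registers epochs from ground
    control points, matches crowns to measure height growth under a set of
    quality filters, detects tree loss by watershed segmentation of the
    canopy-height-model difference, and estimates aboveground-biomass change
    through a height-to-diameter allometry and the Jenkins biomass equation
    with full analytic error propagation validated by Monte Carlo. Includes a
    synthetic-forest simulator that generates paired acquisitions with known
    per-tree growth and removals so every stage can be verified against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    data.table,
    Rcpp,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
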