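Package: dramorph
Title: Localization and Morphometry of the Insect Dorsal Rim Area in 2D and 3D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing and measuring the dorsal rim area (DRA) of
    insect compound eyes by combining calibrated 2D photographs with 3D
    micro-CT reconstructions. Calibrates pixel scale from a glued grid paper,
    measures planimetric DRA area and inter-tegular distance, converts binary
    eye-label volumes to surface meshes and measures total and per-region
    surface areas, estimates a scaled-orthographic camera pose from ocelli
    landmarks to transfer 2D DRA annotations onto the 3D eye surface, extracts
    longitudinal virtual histology slices to measure ommatidial structures
    (lens, crystalline cone, rhabdom) by eye region, and runs the associated
    allometric and nonparametric region-comparison statistics. Includes a
    synthetic-phantom generator with analytic ground truth so the whole
    pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    png,
    tiff,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
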