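Package: stemvol
Title: Individual-Tree Structure and Volume Tables from Near-Field LiDAR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for extracting individual-tree structural parameters from
    paired above-canopy (UAV laser scanning) and under-canopy (backpack laser
    scanning) point clouds of planted forests, and for turning them into stem
    taper equations, standard volume models, and volume tables. Includes a
    synthetic planted-forest simulator with known ground truth, point-cloud
    preprocessing (statistical denoising, progressive TIN ground filtering,
    1-m DEM with inverse-distance-weighted gap filling, height normalization),
    top-down distance-judgement crown segmentation, DBSCAN trunk detection
    with gravity-centre DBH estimation, control-point and tree-pattern rigid
    co-registration, Levenberg-Marquardt taper-equation fitting with volume
    integration, and stand-volume estimation from standard trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
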