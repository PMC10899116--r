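Package: gpseg
Title: Growth-Pattern Segmentation, Grading and Spatial Morphometry for Lung Adenocarcinoma Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-resolution convolutional segmentation network with first- and
    second-order cross-stream attention and pyramid pooling for pixel-level
    delineation of the six lung adenocarcinoma growth patterns (lepidic, papillary,
    acinar, cribriform, micropapillary, solid) on H&E images, together with a
    whole-slide inference pipeline (tiling, Reinhard-style color normalization,
    stitching, majority downsampling, small-component removal), automated IASLC
    grading from pooled pattern proportions, island-level morphometry (area,
    solidity) and an acinar scattering score based on the standard-distance
    dispersion statistic. Includes deterministic synthetic-data generators so the
    whole pipeline is testable end-to-end without slide archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    jsonlite,
    png,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
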