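Package: couchmatch
Title: Automated Measurement of Residual Patient-Positioning Error from
    Paired Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures residual patient-positioning error in image-guided
    radiotherapy by registering a treatment-room digital radiograph (DR)
    against its planning digitally reconstructed radiograph (DRR).
    Captured images are cleaned by inpainting rendered overlay
    annotations and masking the collimator-blocked region via Sobel edge
    scanning; the two views are then aligned by Gaussian-weighted
    zero-mean normalized cross-correlation block matching with subpixel
    refinement, and the frontal/lateral image displacements are mapped
    to lateral/vertical/longitudinal couch-space errors with summary
    statistics.  A procedural pelvic-phantom generator reproduces the
    full couch-shift accuracy experiment with known ground truth, so the
    method can be validated end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
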