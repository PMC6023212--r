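Package: spheromon
Title: Automated Monitoring of Cell Aggregation and Microspheroid
    Formation in Microwell Arrays
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput, bright-field image-based monitoring
    of cell aggregation into microspheroids in agarose microwell arrays.
    Detects cylindrical microwells with a two-stage circular Hough transform
    on a Roberts gradient image, segments the spheroid inside each well by
    combining an adaptive Otsu intensity threshold with a fixed gradient
    threshold followed by a morphological cleanup chain, extracts
    morphological shape descriptors (area, perimeter, axis lengths,
    circularity, roundness), links wells across time-lapse frames into
    per-spheroid trajectories, and summarises population-level aggregation
    kinetics. Includes a synthetic phantom generator with exact ground
    truth that emulates microwell-array time-lapse acquisitions, and
    validation utilities (per-feature relative error, pixel-level
    sensitivity and precision) for quantitative assessment of the
    segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
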