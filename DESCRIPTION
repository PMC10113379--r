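Package: dronestereo
Title: Wide-Baseline Drone Stereo for Millimetre-Scale Plant Height
    Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures crop canopy height from a single pair of overlapping
    nadir drone photographs. The physical baseline between the two exposures
    is recovered from RTK-GNSS fixes by great-circle (haversine) distance,
    the image pair is rectified in flight by a two-phase least-squares
    calibration built on scanline line-pair matching, dense correspondence
    is established by zero-mean normalized cross-correlation (ZNCC) block
    matching, and plant height follows from the disparity difference between
    canopy and surrounding ground. Also provides a baseline-free growth-ratio
    estimator for repeated observations of the same field, and a synthetic
    scene renderer with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml,
    tiff
Config/testthat/edition: 3
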