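Package: nsavision
Title: Automated Neck-Shaft Angle Measurement on Hip Resurfacing Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects a hip resurfacing prosthesis in anterior-posterior (AP)
    and lateral radiograph-like images and measures the radiographic
    neck-shaft angle (NSA). The pipeline converts images to grayscale,
    denoises with an edge-preserving bilateral filter, locates the prosthesis
    by exhaustive mean-squared-error template matching against a reference
    bank, extracts femur-shaft and prosthesis-stem angles with a Hough line
    transform (median-aggregated per region), and fuses the AP and lateral
    NSA estimates with a small fully connected neural network trained against
    clinician trapezoid-technique ground truth. A synthetic-radiograph
    generator with fully known geometry provides testable ground truth for
    every stage, and agreement statistics (Spearman's rank correlation,
    R-squared, mean absolute error, mean squared error) with a shuffled
    repetition protocol quantify accuracy and reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
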