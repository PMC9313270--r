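Package: peakfluo
Title: Real-Time qPCR Signal Processing for Aptamer-Based Protein Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying proteins from real-time PCR amplification
    of aptamer-adaptor complexes. Implements the PeakFluo algorithm
    (per-well background estimation, negative-control subtraction and
    early-stopping detection of the cleaned-signal peak), log-concentration
    standard-curve calibration with an assay-validity gate, the classical
    threshold-cycle estimators (scaled threshold, derivative maxima, Cy0
    tangent and F0 back-projection) for comparison, a four-phase
    amplification-curve simulator, and a small convolutional neural network
    that classifies amplification curves into high/low concentration classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
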