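Package: dicolor
Title: Digital Image Colorimetry with PLS1 Multivariate Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying an analyte from smartphone photographs of
    a colorimetric sensor patch. Extracts mean RGB statistics from a square
    region of interest, expands them into an eight-channel color feature
    vector (R, G, B, intensity, hue, saturation, value, lightness), fits a
    NIPALS PLS1 calibration with leave-one-out cross-validated selection of
    the number of latent components and working-range optimization, and
    computes figures of merit (limit of detection, repeatability, relative
    error against a reference method). Includes a synthetic-data module that
    reconstructs replicate channel tables and renders sensor-patch images
    under a concentration-to-color response model, plus a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    png,
    tiff,
    stats,
    tools,
    utils,
    withr
Suggests:
    jpeg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
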