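Package: nariform
Title: Custom Nostril Retainer Design from Calibrated 2D Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable pipeline for designing patient-specific nostril
    retainers from two-dimensional basilar-view photographs. Implements
    fiducial-marker pixel-to-millimetre calibration (green square of known
    physical size), nostril aperture measurement from line annotations with
    triplicate averaging, anisotropic per-nostril reshaping of a parametric
    two-crura retainer template, watertight triangle-mesh generation with
    binary and ASCII STL export, and the method-agreement statistics
    (Bland-Altman limits of agreement, intraclass correlation, paired
    comparisons with a normality gate) used to validate photograph-derived
    measurements against direct caliper measurements. Includes a synthetic
    basilar-view image and rater-simulation generator with exact ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    jpeg,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
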