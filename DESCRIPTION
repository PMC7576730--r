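Package: elastispec
Title: Elasticity Spectra Analysis for Nanoindentation Force Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Depth-resolved elasticity analysis of nanoindentation
    force-distance curves acquired with spherical probes. Implements
    Savitzky-Golay smoothing, contact-point detection by the ratio of
    variances, conversion to force-indentation curves, the classical
    Hertz fit, pointwise Oliver-Pharr elasticity spectra E(delta), and
    an exponential bilayer model that extracts the stiffness and
    thickness of a stiff surface layer (such as the actin cortex of a
    living cell) together with the bulk elasticity. Includes a
    synthetic-curve generator with known ground truth for validation
    and a batch command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
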