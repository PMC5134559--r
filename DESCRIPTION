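Package: lfeis
Title: Low-Frequency Electrochemical Impedance Spectroscopy for Online
    Biomass Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-processing core for a low-frequency electrochemical
    impedance biomass sensor. Provides a forward equivalent-circuit model
    of electrode, media and double-layer impedance with a constant-phase
    element, a complex nonlinear least-squares (CNLS) fitter that
    extracts double-layer parameters from measured spectra with
    per-parameter error estimates and automatic model reduction, a linear
    calibration layer converting the fitted CPE coefficient into viable
    cell concentration (dry cell weight), quality control for
    negative-differential-resistance artifacts, and a synthetic-data
    generator for spectra and fed-batch cultivation time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
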