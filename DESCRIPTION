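Package: nircal
Title: Near-Infrared Calibration with CARS and Random Frog Wavelength
    Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative calibration of analyte concentrations from
    near-infrared (NIR) absorbance spectra of milk powder. Provides the
    standard spectral pretreatments (standard normal variate,
    multiplicative scatter correction, per-row min-max normalization,
    Savitzky-Golay smoothing), wavelength selection by competitive
    adaptive reweighted sampling (CARS) and the random frog algorithm,
    calibration by cross-validated partial least squares regression and
    radial-basis-kernel support vector regression with an exhaustive
    (C, gamma) grid search, and calibration/prediction-set evaluation via
    Rc, RMSEC, Rp and RMSEP. A synthetic spectrum generator with planted
    Gaussian absorption bands, multiplicative scatter, baseline drift
    and noise supports testing and benchmarking of the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
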