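Package: hsical
Title: Calibration, Characterization and Verification of Push-Broom
    Hyperspectral Imaging Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating and characterizing push-broom (line-scan)
    hyperspectral imaging systems in the 400-1000 nm range used for biological
    imaging. Provides cubic wavelength calibration from gas-discharge lamp
    spectra with iterative line assignment, spatial pixel-pitch and
    resolving-power calibration from Ronchi and USAF1951 targets, estimation
    of spectral smile, keystone, illumination homogeneity and temporal
    stability of LED illumination, and verification against a reference
    spectrometer through normalized absorbance. A forward instrument
    simulator with configurable dispersion, slit broadening, smile, keystone,
    vignetting, noise and warm-up drift makes the whole protocol exercisable
    without hardware. Results are returned as tibbles, with tidy(), glance()
    and autoplot() methods for fitted calibration objects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
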