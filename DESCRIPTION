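Package: fluoroshield
Title: Monte Carlo Scatter Dosimetry for Perforated Radiation Shields in
    Fluoroscopy-Guided Procedures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel Monte Carlo photon transport in the diagnostic energy range
    (5-150 keV) for occupational dosimetry in fluoroscopy-guided structural
    heart interventions. Builds voxelized operating-room scenes with an
    undertable X-ray source, stylized patient and anesthesiologist phantoms and
    a freestanding perforated lead shield; transports photons by Woodcock delta
    tracking with free-electron Klein-Nishina Compton sampling and a kerma
    (suppressed electron transport) approximation; scores per-voxel absorbed
    dose, body-surface region-of-interest dose rates and air dose-rate maps at
    operator-relevant heights; and converts simulated per-photon doses to
    absolute dose rates through a zero-intercept measured-versus-simulated
    calibration fit. Includes a filtered x-ray tube spectrum model, embedded
    photon attenuation tables, synthetic-data generators for calibration and
    scaled operating-room studies, and a study pipeline comparing shield
    aperture patterns across clinical beam projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
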