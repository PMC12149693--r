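Package: promptgamma
Title: Prompt Gamma-Ray Emission Simulation and Spectral Analysis for
    Proton-Therapy Range Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates discrete prompt gamma-ray (PG) emission from proton
    irradiation of tissue-equivalent targets such as PMMA, and analyses the
    resulting spectra the way prompt gamma-ray spectroscopy (PGS) experiments
    do. Protons are transported in the continuous-slowing-down approximation
    with a Bethe stopping-power model; discrete de-excitation lines (carbon
    4.44 MeV, oxygen 6.13 MeV, and others) are emitted by accept-reject
    sampling against exponentially-modified-Gaussian (EMG) parameterisations
    of line-production cross sections; a parametric detector model produces
    deposited-energy spectra with escape peaks and Gaussian resolution
    broadening. The analysis side re-implements the experimental chain:
    EMG pulse fitting of digitized scintillator traces, quality filtering,
    non-paralyzable dead-time correction, multi-line energy calibration,
    SNIP baseline clipping and region-of-interest Gaussian line fitting,
    yielding line-intensity tables versus beam energy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
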