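Package: cardioresp
Title: Time-Varying Cardiorespiratory Coupling from Two-Channel Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the interaction between cardiac and
    respiratory oscillations from simultaneously recorded ECG-like and
    respiration-like signals. Implements the synchrosqueezed wavelet
    transform with adaptive ridge tracking for instantaneous phase and
    frequency extraction, wavelet phase coherence with intersubject
    surrogate significance testing, windowed dynamical Bayesian inference
    of a coupled phase-oscillator model with Fourier-series coupling
    functions, and derived measures: n:m phase synchronization via return
    maps, coupling directionality, direct/indirect coupling decomposition,
    respiratory-sinus-arrhythmia shape descriptors, and reconstructed
    coupling-function surfaces. Includes a synthetic-data module that
    generates noisy coupled phase oscillators, ECG/respiration-like
    waveforms with optional sensor artefacts, and age-graded cohorts for
    validation and calibration.
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
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
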