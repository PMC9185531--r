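Package: glucoradar
Title: Contactless Glucose Concentration Estimation from FMCW Radar Beat Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for contactless measurement of
    glucose solution concentration with a 77 GHz frequency-modulated
    continuous-wave (FMCW) radar. A physics-grounded echo simulator (Fresnel
    reflection at the solution interface plus an attenuated metal back-plate
    return in a lossy dielectric) generates complex beat signals whose
    spectral energy grows monotonically with concentration. The package
    implements the zero-padded FFT/PSD energy analysis, empirical mode
    decomposition and db10 discrete-wavelet denoising, least-squares
    energy-versus-concentration calibration with a power-cycle drift
    diagnostic, complex continuous-wavelet scalogram feature tensors, a small
    convolutional + bidirectional LSTM concentration classifier trained with
    momentum SGD, and sparrow-search hyperparameter optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
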