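Package: remstim
Title: Closed-Loop Auditory Stimulation and Analysis of REM Sleep Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing eye-movement-locked auditory
    stimulation during rapid-eye-movement (REM) sleep. Provides a seeded
    synthetic polysomnography generator (EOG saccades, stage-dependent EEG
    background with click-evoked potentials and band-power modulations, EMG
    atonia, behavioural task datasets), a Chebyshev type II band-pass filter
    bank in causal and zero-phase modes, a streaming eye-movement detector
    with refractory and stage gating, sleep-architecture summaries and
    phasic/tonic REM metrics, trial epoching with artifact exclusion rules,
    spherical-spline channel interpolation, Morlet-wavelet event-related
    spectral perturbation with single-trial decibel baselines,
    suprathreshold-cluster permutation statistics, psychometric threshold
    estimation, and robust regression with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    MASS,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
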