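Package: sknahrv
Title: Skin Nerve Activity and Heart Rate Variability Analysis for Autonomic Dysreflexia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for extracting skin sympathetic nerve activity (SKNA) from
    high-rate ECG recordings and relating it to heart rate variability (HRV)
    and blood pressure during autonomic dysreflexia (AD) episodes after
    spinal cord injury. Implements the SKNA processing chain (downsampling,
    500 Hz high-pass, 100 ms rectified integration), dual-threshold burst
    detection on the mean-normalized amplitude envelope, time-domain HRV
    features (RMSSD, median NN), Lomb-Scargle band powers in rat-specific
    VLF/LF/HF bands, FFT spectrograms and dominant-frequency analysis,
    marker-anchored AD event detection from systolic blood pressure and
    heart rate, and per-feature onset-delay estimation relative to the
    colorectal distension stimulus. A seeded multichannel simulator
    generates rat-like telemetry (ECG with SKNA burst trains, SBP, stimulus
    marker) with known ground truth so that every stage is testable without
    animal recordings.
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
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
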