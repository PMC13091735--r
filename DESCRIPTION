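Package: assr
Title: Quantification of 40 Hz Auditory Steady-State Responses Across
    EEG, OPM and SQUID Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the 40 Hz auditory steady-state response
    (ASSR) in multichannel electrophysiology. Provides a seeded synthetic
    generator of continuous EEG, optically-pumped-magnetometer (OPM) and
    SQUID magnetoencephalography recordings with stimulus schedules, 1/f
    background, line noise and ocular/muscle artifacts; a reproducible
    preprocessing chain (epoching, zero-phase Butterworth filtering,
    automated trial/channel screening, ICA-based ocular cleanup); a
    covariance-maximizing canonical-correlation spatial filter with
    polarity correction and channel-subset selection; spectral signal-to-
    noise ratio and inter-trial phase-coherence (ITPC) statistics with
    chronological trial-count curves; and repeated-measures ANOVA with
    Mauchly sphericity testing, Greenhouse-Geisser correction, partial eta
    squared and Tukey HSD post hoc contrasts. An end-to-end study pipeline
    orchestrates simulation through group statistics under a single master
    seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ica,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
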