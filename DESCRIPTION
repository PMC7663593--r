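Package: rgstress
Title: Relative-Gamma EEG Stress Biomarker Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-channel EEG recorded during a
    structured stress-and-relaxation protocol (resting state, Montreal
    Imaging Stress Task, relaxation, resting state). Implements zero-phase
    Butterworth band-pass and notch filtering, two-second epoching with
    amplitude-based artifact zeroing, per-epoch band power via the
    periodogram, and the relative gamma stress biomarker (gamma power over
    summed alpha and theta power), together with responder-polarity
    handling, group grand-average curves with standard errors, sixth-degree
    polynomial fits, Pearson correlations with Fisher-z confidence
    intervals, exact Wilcoxon signed-rank tests and a Monte-Carlo
    Lilliefors normality test for self-perceived stress surveys. A
    protocol-aware synthetic EEG generator (band-limited Gaussian noise
    with stress-modulated band amplitudes, amplitude artifacts and 50 Hz
    line noise) makes the whole pipeline testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    data.table
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
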