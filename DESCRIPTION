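Package: rockpsg
Title: Sleep EEG Analysis for Rocking-Bed Polysomnography Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for nocturnal sleep EEG studies of vestibular
    (rocking-bed) stimulation. Simulates multi-night polysomnography cohorts
    with known ground truth, detects sleep spindles (amplitude-threshold
    method on the rectified sigma-filtered signal) and slow-oscillation
    half-waves (zero-crossing segmentation after a Chebyshev type II
    band-pass cascade), computes Hanning-windowed FFT band power and the
    delta build-up curve, derives hypnogram-based sleep-architecture metrics
    over full-night and stimulation windows, scores a word-pair declarative
    memory task, and runs the condition-comparison statistics
    (randomized-block ANOVA with LSD post hocs, pooled-SD Cohen's d with
    small-sample correction, Bonferroni-corrected Pearson correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
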