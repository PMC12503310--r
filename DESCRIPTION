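Package: entrainEEG
Title: Analysis of Flicker-Induced 60 Hz Neural Entrainment in Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying steady-state visual entrainment of EEG to
    60 Hz flickering-light stimulation. Provides a seeded multichannel EEG
    simulator with closed-form ground truth, the standard preprocessing chain
    (50 Hz notch, 0.5-80 Hz zero-phase Butterworth band-pass, average
    reference, sync-based session segmentation, amplitude-threshold artifact
    masking), baseline-normalized 60 Hz band-power estimation with Welch
    periodograms and short-time Fourier dynamics, phase-locking-value
    synchrony matrices from Hilbert analytic phase, regional aggregation, the
    nonparametric group-inference stack (Shapiro-Wilk gate, Wilcoxon rank-sum,
    Kruskal-Wallis with exact small-sample enumeration, Dunn-Bonferroni post
    hoc, Fisher's exact test, two-way ANOVA), and cohort-level orchestration
    with biomarker fold-change and tolerability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'biomarkers.R'
    'stats.R'
    'preprocess.R'
    'plv.R'
    'spectral.R'
    'cohort.R'
    'entrainEEG-package.R'
    'io.R'
    'simulate.R'
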