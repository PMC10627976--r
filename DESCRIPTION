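Package: ppafuse
Title: Spectral Power and Preferred-Phase-Angle Fusion Classification for
    Multichannel Neurophysiological Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Band-wise spectral features for multichannel electrophysiological
    recordings (MEG/EEG): Welch band power in decibels and the preferred phase
    angle (PPA), the circular mean direction of within-band Fourier phases,
    with its phase-consistency modulus. Provides t-test feature ranking with
    p-value-threshold sweeps, a small feedforward neural-network classifier
    with validation-based early stopping, subject-exclusive nested fivefold
    cross-validation, feature-level and weighted score-level fusion with a
    score-correlation complementarity check, exact binomial chance levels, and
    a seeded synthetic two-class oscillatory cohort generator with von Mises
    phase clustering for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
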