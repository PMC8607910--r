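Package: ibsync
Title: Speaker-Listener Interpersonal Brain Synchronization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dyadic (speaker-listener) EEG hyperscanning
    studies of emotional story sharing. Provides preprocessing of continuous
    multichannel EEG (band-pass and notch filtering, mastoid re-referencing,
    downsampling, fixed-length epoching, amplitude-based artifact rejection),
    phase-locking value (PLV) computation per electrode pair and frequency band,
    region-of-interest summaries and emotion-minus-neutral contrasts, group
    statistics (pooled-variance t tests, Cohen's d, FDR/Bonferroni correction,
    correlations, simple-slopes moderation), directional coupling via
    time-domain Granger causality on baseline-normalized signals, and
    epsilon-SVR prediction of interpersonal closeness with permutation
    significance. A synthetic-dyad generator with von Mises phase-difference
    coupling supplies recovery-testable inputs with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
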