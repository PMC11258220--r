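Package: phrasetrack
Title: Frequency-Tagged EEG Analysis of Phrase-Rate Neural Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for frequency-tagging EEG experiments on the
    neural tracking of multi-word phrases in isochronous speech. Provides a
    synthetic cohort generator with known spectral ground truth (phase-locked
    word-rate and phrase-rate components over 1/f background noise), stimulus
    stream construction with acoustic verification via the envelope power
    spectrum, epoch-level preprocessing (epoching, mastoid re-referencing,
    zero-phase bandpass filtering, channel interpolation, subject-level
    quality control), spectral estimation (whole-epoch DFT, evoked power,
    inter-trial phase coherence), and condition-level inference (permutation
    tests for spectral peaks against neighboring-bin baselines, paired
    comparisons with false-discovery-rate correction, 2x2 repeated-measures
    ANOVA with Tukey-adjusted contrasts on estimated marginal means, and a
    bigram transitional-probability control regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
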