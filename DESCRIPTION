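Package: photomotor
Title: Fiber Photometry and Locomotor Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of frequency-multiplexed fiber photometry
    recordings together with open-field pose tracking. Recovers calcium and
    isosbestic fluorescence envelopes by software lock-in demodulation,
    corrects motion artifacts by isosbestic subtraction, detrends and
    normalizes signals to per-recording Z-scores, detects locomotor bouts
    from body-center speed, aligns neural activity to sensory stimuli (raw
    time) and to motor events (duration-normalized time), and applies an
    assumption-gated statistical layer (repeated-measures ANOVA or Friedman
    test with Student-Newman-Keuls post hoc, paired comparisons, speed-bin
    and habituation regressions). A synthetic-session generator with
    exported ground truth makes every stage verifiable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
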