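Package: tempseg
Title: Temporal Segmentation Psychophysics: Stimuli, Staircases, Curve
    Fits, and Reading-Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for temporal-segmentation
    psychophysics. Generates temporally segmented and temporally
    intermingled random-dot motion sequences and streak-form images, runs
    3-down 1-up adaptive staircases against parametric two-interval
    forced-choice observers, fits two-limbed (broken-stick) threshold
    versus segment-duration curves, and analyses participant cohorts with
    a correlation-matrix PCA composite reading score and normality-gated
    semipartial correlations controlling gender and nonverbal IQ. A
    calibrated synthetic-cohort generator makes the entire pipeline
    testable end to end without human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
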