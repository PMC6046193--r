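Package: syncstop
Title: Sensorimotor Synchronization Combined with the Stop-Signal Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a combined sensorimotor-synchronization
    and stop-signal paradigm. Provides a generative horse-race model of
    participants who tap or vocalize in time with an auditory pacing signal
    while occasionally withholding responses to visual stop signals, an
    adaptive one-up-one-down stop-signal-delay staircase, device-timing
    calibration, asynchrony and go-type classification, proactive-inhibition
    difference scores, integration-method stop-signal reaction time (SSRT)
    estimation with race-model assumption checks, and a repeated-measures
    inference layer (within-subject ANOVA with Greenhouse-Geisser correction,
    paired t tests, Bonferroni post hocs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
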