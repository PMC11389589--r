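Package: vmrloc
Title: Hand-Localization Precision During Early Visuomotor Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cyclic visuomotor-rotation experiments that
    probe the precision of unseen-hand localization during early motor
    adaptation. Provides a paradigm simulator (cycle-structured schedules,
    state-space learner, minimum-jerk reach trajectories, pointer and
    two-alternative forced-choice localization reports), kinematic event
    detection and reach features, trial-screening rules, robust bias/IQR
    localization summaries, logistic psychometric fits (PSE, JND) with
    two-target alignment pooling, and an iterative variability-matching
    control analysis. Exports tidy per-subject tables for inferential
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
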