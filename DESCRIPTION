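Package: vmrlearn
Title: Visuomotor Rotation Learning Under Reward and Punishment with EEG
    Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-block visuomotor rotation reaching task with
    reward or punishment point feedback, generates go-cue-locked and
    feedback-locked epoched EEG with planted event-related
    desynchronization (ERD) and feedback-related negativity (FRN) ground
    truth, extracts sensorimotor ERD and frontal FRN features, computes
    learning and retention metrics, and runs the individual-differences
    inference chain: mixed two-way ANOVA with Mauchly/Greenhouse-Geisser
    sphericity handling, Holm-corrected post hoc tests, Lasso regression
    with 5-fold cross-validation and the one-standard-error rule followed
    by a final OLS fit, and fixed-model multiple-regression power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
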