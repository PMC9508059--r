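Package: slonline
Title: Online Measurement of Implicit Visual Statistical Learning in
    Serial Reaction Time Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing serial
    reaction time (SRT) experiments that measure implicit visual
    statistical learning online.  Provides constrained pseudo-random
    stimulus-sequence generation with verifiable transition-probability
    structure (associated stimulus pairs embedded among single control
    stimuli), a generative synthetic observer with subject, picture and
    sequential-accuracy variance components plus priming and
    motor-confound effects, the standard trial-exclusion cascade for
    reaction-time data, repeated-measures group statistics with
    Tukey-Kramer and Wilcoxon post hoc tests, mixed-effects
    learning-trajectory models with estimated-marginal-mean trend
    contrasts, a linear-versus-logarithmic encompassing model
    comparison, and Monte-Carlo power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    emmeans,
    car,
    lmtest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
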