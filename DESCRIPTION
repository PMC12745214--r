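Package: icftraj
Title: Trajectory and Cost-Effectiveness Analysis of ICF Disability Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal disability assessments scored
    with a 20-item instrument based on the International Classification of
    Functioning, Disability and Health (ICF). Provides a censored-normal
    group-based trajectory model (GBTM) fitted by expectation-maximisation
    with BIC, average-posterior-probability and minimum-share model
    selection; item-level dysfunction and improvement summaries;
    trajectory-group comparison statistics (Pearson chi-square, exact r x c
    tests, one-way ANOVA, Kruskal-Wallis) and proportional-odds ordinal
    regression with parallel-lines and goodness-of-fit diagnostics;
    rehabilitation cost-effectiveness indices (effect, efficiency and
    benefit); and a synthetic longitudinal-cohort generator for testing the
    full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
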