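Package: cprquality
Title: Chest Compression Quality Analysis for Simulated Advanced Life Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of chest-compression quality from time-stamped
    compression event streams recorded during (simulated) advanced life
    support. Summarises compression depth and rate per minute over a
    12-minute analysis span, classifies each resuscitation attempt as
    good, bad, or showing decay (the operational proxy for rescuer
    fatigue) independently for depth and rate, detects hands-off pauses
    and computes the no-flow ratio overall and in three-minute periods,
    and tests the no-flow trend with a one-way repeated-measures ANOVA
    and Bonferroni-adjusted paired t-tests. Includes a synthetic
    event-stream generator with provider-specific baselines, linear
    fatigue decay, and a scenario pause schedule, plus a fixed-seed
    19-attempt reference cohort for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
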