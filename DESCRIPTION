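Package: ankleEE
Title: Energy Expenditure Calibration and Validation for Ankle-Worn
    Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and validating physical-activity energy
    expenditure (EE) from ankle-mounted triaxial accelerometer counts and
    heart-rate telemetry against indirect calorimetry. Implements the Weir
    equation for criterion EE, the Freedson VM3 combination equation,
    published ankle-specific linear corrections with and without a
    heart-rate-reserve term, steady-state epoch trimming, de-novo
    calibration-model fitting with 70/30 cross-validation, and a full
    method-agreement battery (paired t, Cohen's d, MAPE, Pearson r,
    absolute-agreement ICC, one-way ANOVA with Bonferroni post-hoc). A
    synthetic treadmill-trial generator reproduces the group-level
    statistical structure of a four-group fitness cohort so the entire
    pipeline can be exercised without device data.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
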