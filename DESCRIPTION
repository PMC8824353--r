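Package: dietspan
Title: Life-Expectancy Impact of Sustained Dietary Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-support model estimating how sustained changes in the
    intake of 14 food groups alter remaining life expectancy by age, sex and
    region. Builds single-year period life tables from age-grouped all-cause
    mortality rates, applies dose-response hazard ratios for diet changes with
    a linear time-to-full-effect ramp, computes Monte-Carlo uncertainty
    intervals (uniform draws within the hazard-ratio confidence bands), a
    conservative-to-radical sensitivity family, an energy-feasibility gate,
    and an evidence-quality (NutriGrade) weighted score. Ships a synthetic
    Gompertz-Makeham fixture generator and a brute-force cohort simulation
    oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
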