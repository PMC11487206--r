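Package: frailscreen
Title: Wearable-Based Frailty and Falls-Risk Screening Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates older-adult cohorts with ankle-worn accelerometer and
    interval-sampled heart-rate streams, and analyses them with three wearable
    screeners: a gait analyzer (step detection, 40-step walking bouts, cadence
    and gait-quality features, an integer gait risk score), a daily-living
    analyzer (epoch energy normalized to 1-step/second walking, three intensity
    bands, daily kilocalorie classes), and a heart-rate analyzer (automated
    heart-rate-recovery episodes averaged per participant). Clinical reference
    standards (FRAIL with its functional/nonfunctional split, SPPB and its
    gait-plus-balance subset, timed up and go, 4-m gait speed, FROP-Com, fall
    history) are scored and dichotomized, and each screener is validated
    against each standard with 2x2 diagnostic tables, ROC curves swept over
    cutoffs, Youden-optimal thresholds and trapezoidal AUC.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
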