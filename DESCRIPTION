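Package: actirhythm
Title: Rest-Activity Rhythm, Actigraphic Sleep, and Heart Rate Variability
    Analysis for Acute Coronary Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing minute-epoch wrist actigraphy and RR-interval
    recordings from intensive-care cardiac cohorts. Computes the nonparametric
    circadian indicators of the rest-activity rhythm (interdaily stability,
    intradaily variability, M10, L5, relative amplitude, the actigraphic
    dichotomy index), scores sleep/wake from activity to derive sleep onset
    latency, total sleep time, sleep efficiency, wake after sleep onset and
    awakenings, and computes time-domain and Poincare heart rate variability
    metrics together with the deceleration capacity of heart rate. Includes a
    synthetic-cohort generator with known ground-truth rhythm parameters for
    validation by parameter recovery, and covariate-adjusted group comparison
    and (partial) correlation reporting for case-control and prognosis
    analyses.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
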