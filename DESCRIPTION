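Package: twinsleep
Title: Interval-Censored Weibull Frailty Models for Twin-Cohort Sleep Duration Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-run trends in self-reported sleep
    duration from repeated mailed questionnaires in a twin cohort. Ordinal
    sleep-duration responses are treated as interval-censored observations of
    a latent continuous duration and fitted with a Weibull proportional-hazards
    regression with nested log-normal random effects (twin pair, individual),
    estimated by maximum likelihood with nested Gauss-Hermite quadrature.
    Includes Turnbull nonparametric survival estimation for interval-censored
    categories, midpoint-coded descriptive summaries and trend statistics, a
    synthetic twin-cohort generator mirroring the survey design, and a
    pipeline that assembles all outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    survival,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
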