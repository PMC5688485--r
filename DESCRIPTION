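Package: anclink
Title: Linking Household Surveys and Health Facility Assessments to
    Estimate Antenatal Care Intervention Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population-level "availability coverage" of
    antenatal care interventions (syphilis detection and treatment; case
    management of diabetes, hypertensive disorders, malaria and
    pre-eclampsia) by linking household-survey care-seeking to health
    facility readiness at the stratum level (facility type x managing
    authority x urban/rural location). Provides a seeded synthetic-data
    generator emulating DHS-style household records and SPA/SARA-style
    facility rosters with known ground truth, weighted stratum
    summaries, the stratum-product linking estimator, fractional-logit
    (quasi-binomial) predictive models with robust standard errors and
    stepwise covariate selection, the tiered and flat default proxy
    rules used by the Lives Saved Tool, and model evaluation metrics
    (R-squared, Pearson correlation, RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
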