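Package: lactload
Title: Normalized Lactate Load and 28-Day Mortality in ICU Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes time-weighted lactate burden statistics (lactate load
    and normalized lactate load) from irregularly timed serial lactate
    measurements in the first hours of an ICU stay, and evaluates their
    ability to predict 28-day mortality. Provides the full analysis
    pipeline around the statistic: an eligibility cascade with a filter
    report, sepsis / non-sepsis cohort stratification, nonparametric ROC
    analysis with DeLong variance estimation for paired and unpaired AUC
    comparisons, Youden-index cutoffs with operating characteristics
    (sensitivity, specificity, likelihood ratios, predictive values and
    exact confidence intervals), normality-gated descriptive group
    comparisons, a measurement-count sensitivity analysis, and a synthetic
    ICU cohort generator so the pipeline can be exercised without access
    to restricted clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
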