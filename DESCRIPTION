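Package: uramr
Title: One-Sample Mendelian Randomization of Serum Uric Acid on Metabolic Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for one-sample, single-SNP Mendelian
    randomization of serum uric acid on incident metabolic syndrome and its
    four components in longitudinal health check-up cohorts. Provides
    phenotyping under the Chinese Diabetes Society 2004 criteria, cohort and
    subcohort construction from repeated check-up records, age-band z-score
    standardization of the exposure, a Hardy-Weinberg equilibrium test, linear
    and logistic association fits, a self-contained Cox proportional-hazards
    estimator with Efron tie handling, the Wald-ratio instrumental-variable
    estimator with delta-method standard errors, and a calibrated synthetic
    cohort generator so that every stage of the analysis is testable without
    access to private cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
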