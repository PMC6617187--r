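Package: pcatriage
Title: Integrated Risk and Life-Expectancy Triage for Prostate Biopsy Referral
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for referral to prostate biopsy in primary care.
    Combines a logistic regression model for the risk of clinically significant
    prostate cancer (ISUP grade 2 or higher) on biopsy with Weibull
    life-expectancy estimates with and without untreated disease, converts a
    trial all-cause-mortality hazard ratio into an absolute survival gain from
    treatment, and applies consensus threshold bands to produce a three-level
    referral recommendation. Includes the model-selection machinery
    (optimism-corrected concordance index, index of prediction accuracy,
    decision-curve analysis) and seeded synthetic cohort generators so the
    full pipeline is testable without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
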