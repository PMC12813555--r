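Package: oudcontrols
Title: Comparing Control Definitions for Opioid Use Disorder Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the choice of control group shapes
    association results in electronic-health-record (EHR) studies of opioid
    use disorder (OUD). Implements the temporal prescription-window
    classifier that separates unexposed, minimally exposed and chronic-use
    prescription patterns; case and control phenotyping with a medical-home
    data floor and cancer/age exclusions; phecode mapping with a minimum-case
    filter; exact-stratum ratio matching on demographics and median age of
    record; per-site logistic PheWAS with inverse-variance fixed-effects
    meta-analysis and I-squared heterogeneity; a covariate-adjusted variant
    association scan with genomic-inflation diagnostics; and a summary-
    statistic effect-size dilution estimator with bootstrap confidence
    intervals. A synthetic longitudinal EHR and genotype generator with a
    known truth record makes every stage testable end to end without access
    to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
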