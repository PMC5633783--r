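Package: cortatrophy
Title: Regional Cortical Atrophy Statistics for Traumatic Brain Injury Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate statistical analysis linking acute traumatic
    brain injury severity (Glasgow Coma Score-Extended and acute seizure
    occurrence) to region-wise longitudinal cortical atrophy and to
    six-month functional outcome (Glasgow Outcome Score-Extended).
    Implements the two-step procedure: per-region multivariate linear
    regression with Wilks' lambda to F inference, permutation validation
    and Benjamini-Hochberg false discovery rate correction, followed by
    per-region Pearson correlation of relative atrophy with outcome.
    Includes Cohen's f-squared effect sizes, noncentral-F power analysis
    with minimum-effect and minimum-sample solvers, a synthetic cohort
    generator with lesion-driven block missingness for validation, and a
    reproducible end-to-end pipeline with tabular input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
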