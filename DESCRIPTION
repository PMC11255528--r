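Package: ehrdqa
Title: Data Quality Assessment for Paired Paper and Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the quality of electronic health record (EHR)
    data against the paper charts they were transcribed from, as practised in
    facility-level HIV programme evaluations. Implements missing-value and
    standardization rules (sentinel dates, antiretroviral regimen
    canonicalization, viral-load tolerance matching), date-keyed alignment of
    longitudinal viral-load entries, completeness/matching/concordance metrics
    with lot-quality-assurance-sampling (LQAS) thresholding at facility level,
    and the association analyses linking data quality to facility
    characteristics and clinical-alert status (Pearson correlations with
    Bonferroni correction; 2x2 chi-square with continuity correction and phi
    effect size). A synthetic dual-source record generator with configurable
    error processes supports end-to-end testing and calibration without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
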