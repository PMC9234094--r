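Package: perisurv
Title: Facility-Based Perinatal Outcome Surveillance Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-site facility-based surveillance of
    adverse perinatal and neonatal outcomes. Classifies births against
    standardized outcome definitions (low birthweight, preterm birth, small
    for gestational age, congenital microcephaly, stillbirth, neonatal death
    and neonatal infection), estimates site-specific rates per 1,000 births
    with exact Clopper-Pearson intervals, quantifies routine-surveillance
    case ascertainment against rule-based re-identification, and computes
    minimum detectable relative risks and odds ratios for planning cohort
    and case-control vaccine-safety studies, including scenario grids. A
    configurable synthetic line-list generator reproduces the statistical
    structure of a multi-country facility network so the full pipeline runs
    and tests without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
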