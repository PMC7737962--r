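Package: hesbirths
Title: Birth Cohorts from Hospital Episode Data with Linkage-Error Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving a national cohort of singleton live births
    from Hospital Episode Statistics (HES)-style admitted-patient-care
    extracts and for quantifying how changes to patient-identifier
    collection affect linkage of births to follow-up hospital and mortality
    records. Includes episode-to-admission merging with a one-day transfer
    tolerance, infant readmission and mortality outcome construction from
    linked ONS-style death registrations, segmented interrupted
    time-series regression around pre-specified change points, coverage
    reporting against national birth statistics, and a synthetic-data
    generator that emulates era-dependent identifier failure so the whole
    pipeline runs and is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
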