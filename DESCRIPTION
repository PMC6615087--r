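Package: advcrc
Title: Incidence of Advanced Colorectal Cancer from Claims and Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate age-standardized incidence rates (ASIRs) of
    advanced colorectal cancer from two complementary sources: longitudinal
    health-claims data, via a temporal case-ascertainment and staging
    algorithm (incident-case washout, quarter-based confirmation and
    metastasis-code windows), and cancer-registry TNM records, via a
    classification scheme with explicit missing-data scenarios. Includes
    direct age standardization to the old European Standard Population,
    comparison and trend analyses between the two sources, and a seeded
    synthetic-data generator that emulates German claims structure
    (quarter-granular outpatient coding, dated inpatient diagnoses,
    insurance gaps, prevalent cancers, registry TNM missingness) so every
    stage of the pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
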