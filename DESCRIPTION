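Package: cdmcurate
Title: Data Curation and Quality Checking for Common Data Model DataMarts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A research-readiness ("foundational data curation") engine for
    electronic health record data harmonized to a PCORnet-style common data
    model (CDM). Provides a declarative, config-driven CDM schema; a
    versioned catalog of data-quality checks in four categories
    (conformance, completeness, plausibility, persistence) with
    threshold-based exception detection and required/investigative
    approval gating; refresh-history persistence and latency analysis;
    descriptive statistics (frequencies, crosstabs, missing/non-missing/
    distinct counts, monthly volume series); empirical data curation (EDC)
    style reports and network-level summaries; and a seeded synthetic
    DataMart generator with injectable, audit-logged data defects so the
    whole system is testable without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
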