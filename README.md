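# cdmcurate

Foundational data curation for EHR common-data-model DataMarts.

Distributed clinical research networks harmonize each partner's electronic
health record data into a common data model (CDM); every quarter the
partner re-extracts ("refreshes") its DataMart and runs a standardized
curation query before the data may serve any network study. `cdmcurate`
implements that research-readiness engine for data-quality engineers and
informatics teams:

* a **declarative CDM schema** (YAML-driven; packaged 8-table PCORnet-style
  core: DEMOGRAPHIC, ENCOUNTER, DIAGNOSIS, PROCEDURES, PRESCRIBING,
  LAB_RESULT_CM, VITAL, DEATH) with structural validation;
* a **versioned catalog of data checks** in the four Kahn-style categories
  — conformance, completeness, plausibility, persistence — where a check
  is a broad rule and a *measure* its instantiation on one table/field/
  stratum. The packaged `cycle16` catalog holds 46 checks (`cycle7`: 36);
* **threshold-based exception detection**: most checks test an error
  proportion against the network default of < 5% of records in error
  (pass iff `numerator/denominator < 0.05`); latency checks use a months
  metric (≤ 3), persistence checks a relative-change metric (drop ≤ 5% vs
  the prior refresh), ratio checks a closed plausibility band;
* **approval gating**: a refresh is approved iff it has zero *required*
  check exceptions; *investigative* exceptions must be investigated but do
  not block;
* the **descriptive-statistics layer** of the curation query: a 10-year
  lookback window, frequencies, crosstabs by year, missing/non-missing/
  distinct counts, monthly volume series;
* **EDC-style reports** (markdown/HTML/JSON), network summaries across
  DataMarts and cycles, and the refresh-by-refresh exception grid
  (exception / pass / not-submitted cells);
* a **seeded synthetic DataMart generator** with ten injectable defect
  modes (future dates, illogical dates, implausible values, field
  missingness, unmapped RxNorm term types, missing LOINC codes and lab
  units, duplicate keys, orphan records, omitted principal-diagnosis
  flags), each logged in an audit log so measured check numerators can be
  validated against injected truth exactly.

## Worked example

Generate a synthetic DataMart with 20% of lab results missing their
result unit, then curate it:

```r
library(cdmcurate)

schema  <- load_schema()                 # packaged 8-table core schema
catalog <- load_catalog("cycle16")       # 46 checks

pop     <- population_config(n_patients = 300, seed = 42)
refresh <- generate_datamart(pop, error_profile(missing_lab_unit_rate = 0.2))
refresh
#> <datamart_refresh> DM01 ordinal 1 on 2024-12-31
#>   DEMOGRAPHIC     300 records
#>   ENCOUNTER       1772 records
#>   DIAGNOSIS       3571 records
#>   PROCEDURES      1784 records
#>   PRESCRIBING     1783 records
#>   LAB_RESULT_CM   2691 records
#>   VITAL           1423 records
#>   DEATH           6 records

outcome <- run_curation(refresh, NULL, catalog, schema)
outcome
#> <curation_outcome> DM01 refresh 1
#>   required exceptions: 0, investigative: 1 -> APPROVED

m <- outcome$measures
m[m$check_id == "DC3.12", c("table", "field", "numerator", "denominator",
                            "proportion", "status")]
#>             table       field numerator denominator proportion    status
#> 146 LAB_RESULT_CM RESULT_UNIT       532        2691   0.197696 exception
```

The lab-units check (DC3.12) flags the refresh — 532 of 2,691 quantitative
lab results (19.8%) lack a valid unit, beyond the 5% threshold — but since
it is an investigative check the refresh is still approved. The 532
flagged records are exactly the records the generator's audit log says
were injected (`refresh$audit`). Removing the error profile yields a
refresh that passes all 46 checks.

A shell front end wraps the same functions:

```sh
Rscript inst/cli/cdmcurate.R generate --out dm --n-patients 300 --seed 42
Rscript inst/cli/cdmcurate.R curate --refresh-dir dm --out run1 --gate
```

`curate --gate` exits non-zero when the refresh is not approved.

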