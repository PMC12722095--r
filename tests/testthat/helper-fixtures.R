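# Shared fixtures, memoised so expensive generations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

test_schema <- function() memo("schema", load_schema())
test_catalog <- function() memo("catalog16", load_catalog("cycle16", test_schema()))

# A clean refresh large enough that every check passes comfortably.
clean_refresh <- function() {
  memo("clean_refresh",
       generate_datamart(population_config(n_patients = 200, seed = 101)))
}

clean_outcome <- function() {
  memo("clean_outcome",
       run_curation(clean_refresh(), NULL, test_catalog(), test_schema()))
}

# Minimal hand-built refresh for boundary tests: one patient, `n_enc`
# encounters (admit dates supplied), optional diagnoses/procedures.
tiny_refresh <- function(refresh_date = as.Date("2024-12-31"),
                         admit = as.Date("2024-06-01"),
                         discharge = NULL, enc_type = "IP",
                         dx_date = NULL, px_date = NULL) {
  n <- length(admit)
  if (is.null(discharge)) discharge <- as.Date(rep(NA, n))
  enc <- data.frame(
    ENCOUNTERID = sprintf("E%03d", seq_len(n)), PATID = "P001",
    ADMIT_DATE = admit, DISCHARGE_DATE = discharge,
    ENC_TYPE = rep_len(enc_type, n), FACILITYID = "FAC1",
    DISCHARGE_DISPOSITION = ifelse(rep_len(enc_type, n) %in% c("IP", "EI", "IS"),
                                   "A", ""),
    stringsAsFactors = FALSE)
  tabs <- list(
    DEMOGRAPHIC = data.frame(PATID = "P001",
                             BIRTH_DATE = as.Date("1970-01-01"),
                             SEX = "F", HISPANIC = "N", RACE = "05",
                             stringsAsFactors = FALSE),
    ENCOUNTER = enc)
  if (!is.null(dx_date)) {
    tabs$DIAGNOSIS <- data.frame(
      DIAGNOSISID = sprintf("D%03d", seq_along(dx_date)), PATID = "P001",
      ENCOUNTERID = rep_len(enc$ENCOUNTERID[1], length(dx_date)),
      DX = "I10", DX_TYPE = "10", DX_DATE = dx_date, PDX = "P",
      stringsAsFactors = FALSE)
  }
  if (!is.null(px_date)) {
    tabs$PROCEDURES <- data.frame(
      PROCEDURESID = sprintf("X%03d", seq_along(px_date)), PATID = "P001",
      ENCOUNTERID = rep_len(enc$ENCOUNTERID[1], length(px_date)),
      PX = "99213", PX_TYPE = "CH", PX_DATE = px_date,
      stringsAsFactors = FALSE)
  }
  new_refresh("TINY", refresh_date, 1L, tabs)
}

# Error profile exercising every injectable mode at a common rate.
all_modes_profile <- function(rate) {
  error_profile(
    future_date_rate = rate, illogical_date_rate = rate,
    implausible_value_rate = rate,
    missing_field_rates = list(ENCOUNTER.DISCHARGE_DISPOSITION = rate,
                               PRESCRIBING.RX_DAYS_SUPPLY = rate),
    missing_principal_rate = rate, unmapped_rx_rate = rate,
    missing_loinc_rate = rate, missing_lab_unit_rate = rate,
    duplicate_key_rate = rate, orphan_record_rate = rate)
}

# (check_id, defect kind) pairs whose numerators must equal the audit log.
oracle_pairs <- list(
  c("DC2.01", "future_date"), c("DC2.02", "implausible_value"),
  c("DC2.03", "illogical_date"), c("DC3.03", "missing_value"),
  c("DC2.07", "missing_principal"), c("DC3.08", "unmapped_rx"),
  c("DC3.09", "missing_loinc"), c("DC3.12", "missing_lab_unit"),
  c("DC1.05", "duplicate_key"), c("DC1.06", "orphan_record"))

# Count oracle mismatches between measured numerators and the audit log.
count_oracle_mismatches <- function(refresh, catalog = test_catalog(),
                                    schema = test_schema()) {
  win <- apply_lookback(refresh, schema)
  a <- refresh$audit
  mismatches <- 0L
  for (p in oracle_pairs) {
    res <- evaluate_check(catalog$checks[[p[1]]], win, NULL, schema)
    for (i in seq_len(nrow(res))) {
      if (is.na(res$numerator[i])) next
      fld <- res$field[i]
      expected <- if (is.na(fld)) {
        sum(a$defect == p[2] & a$table == res$table[i])
      } else {
        sum(a$defect == p[2] & a$table == res$table[i] & a$field == fld)
      }
      if (res$numerator[i] != expected) mismatches <- mismatches + 1L
    }
  }
  mismatches
}
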