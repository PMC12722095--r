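# synthetic_datamart: seeded, CDM-conformant synthetic DataMarts with
# injectable, audit-logged data-quality defects.
#
# Defects are injected post-generation on a clean DataMart and every
# injected defect is logged (table, record key, field, defect kind), so
# measured check proportions can be validated against injected truth
# exactly. A row receives at most one defect; later injection modes only
# sample among rows the audit log has not touched, which keeps every
# per-field numerator equal to its audit count.
#
# Each record carries a hidden facility tag (column ".facility", not a CDM
# field) so feed-loss/-gain refresh events are realizable.

#' Population configuration for the synthetic generator
#'
#' Defaults describe a mid-sized ambulatory-heavy DataMart: three years of
#' data, six encounters per patient per period, two diagnoses and about one
#' lab panel and one prescription per encounter, with a mild linear growth
#' trend and seasonal modulation in monthly encounter volume.
#'
#' @param n_patients number of patients.
#' @param date_range length-2 `Date` (or string) vector, start < end.
#' @param encounters_per_patient,diagnoses_per_encounter,labs_per_encounter,prescriptions_per_encounter,procedures_per_encounter
#'   means of the Poisson count distributions.
#' @param vitals_per_encounter probability an encounter has a vital-sign record.
#' @param enc_type_mix named probability vector over encounter types
#'   (must sum to 1 within 1e-9).
#' @param facility_shares named probability vector of record share per
#'   simulated facility/feed.
#' @param death_rate fraction of patients with a death record
#'   (`round(rate * n)` patients, so fixtures are deterministic in count).
#' @param growth linear growth of monthly encounter volume over the date
#'   range (0.3 = 30% higher at the end than the start).
#' @param seasonal_amp amplitude of the seasonal (annual sine) volume term.
#' @param seed integer RNG seed; everything downstream is deterministic in it.
#' @return a `population_config` list.
#' @export
population_config <- function(n_patients = 500,
                              date_range = as.Date(c("2022-01-01", "2024-12-31")),
                              encounters_per_patient = 6,
                              diagnoses_per_encounter = 2,
                              labs_per_encounter = 1.5,
                              prescriptions_per_encounter = 1,
                              procedures_per_encounter = 1,
                              vitals_per_encounter = 0.8,
                              enc_type_mix = c(AV = 0.55, ED = 0.12, IP = 0.08,
                                               EI = 0.05, OA = 0.05, OS = 0.10,
                                               TH = 0.05),
                              facility_shares = c(FAC1 = 0.30, FAC2 = 0.25,
                                                  FAC3 = 0.15, FAC4 = 0.12,
                                                  FAC5 = 0.10, FAC6 = 0.08),
                              death_rate = 0.02,
                              growth = 0.3, seasonal_amp = 0.05,
                              seed = 1L) {
  date_range <- as.Date(date_range)
  stopifnot(length(date_range) == 2, date_range[1] < date_range[2])
  means <- c(encounters_per_patient, diagnoses_per_encounter, labs_per_encounter,
             prescriptions_per_encounter, procedures_per_encounter)
  if (any(means <= 0)) stopf("all count-distribution means must be > 0")
  if (abs(sum(enc_type_mix) - 1) > 1e-9) stopf("enc_type_mix must sum to 1")
  if (abs(sum(facility_shares) - 1) > 1e-9) stopf("facility_shares must sum to 1")
  structure(list(n_patients = as.integer(n_patients), date_range = date_range,
                 encounters_per_patient = encounters_per_patient,
                 diagnoses_per_encounter = diagnoses_per_encounter,
                 labs_per_encounter = labs_per_encounter,
                 prescriptions_per_encounter = prescriptions_per_encounter,
                 procedures_per_encounter = procedures_per_encounter,
                 vitals_per_encounter = vitals_per_encounter,
                 enc_type_mix = enc_type_mix, facility_shares = facility_shares,
                 death_rate = death_rate, growth = growth,
                 seasonal_amp = seasonal_amp, seed = as.integer(seed)),
            class = "population_config")
}

#' Error profile: injectable data-quality defect rates
#'
#' Every rate is the per-record Bernoulli probability that an in-scope,
#' not-yet-defective record receives that defect. All default to zero; a
#' zero profile yields a refresh with zero check exceptions.
#'
#' @param future_date_rate fraction of encounters whose whole date bundle
#'   (admit/discharge and linked records) is shifted past the refresh date.
#' @param illogical_date_rate fraction of encounters given discharge <
#'   admit, and of procedures dated outside their encounter window.
#' @param implausible_value_rate fraction of vital-sign records given an
#'   out-of-range systolic blood pressure.
#' @param missing_field_rates named list, `"TABLE.FIELD" = rate`, of values
#'   blanked to the missing convention.
#' @param missing_principal_rate fraction of inpatient encounters whose
#'   principal-diagnosis flag is removed.
#' @param unmapped_rx_rate fraction of prescriptions whose RxNorm code is
#'   replaced by an ingredient-level code or blanked.
#' @param missing_lab_unit_rate,missing_loinc_rate fractions of quantitative
#'   lab results losing their unit / LOINC code.
#' @param duplicate_key_rate fraction of encounters duplicated under the
#'   same primary key.
#' @param orphan_record_rate fraction of diagnoses pointed at a nonexistent
#'   encounter.
#' @return an `error_profile` list.
#' @export
error_profile <- function(future_date_rate = 0, illogical_date_rate = 0,
                          implausible_value_rate = 0,
                          missing_field_rates = list(),
                          missing_principal_rate = 0,
                          unmapped_rx_rate = 0, missing_lab_unit_rate = 0,
                          missing_loinc_rate = 0, duplicate_key_rate = 0,
                          orphan_record_rate = 0) {
  rates <- c(future_date_rate, illogical_date_rate, implausible_value_rate,
             missing_principal_rate, unmapped_rx_rate, missing_lab_unit_rate,
             missing_loinc_rate, duplicate_key_rate, orphan_record_rate,
             unlist(missing_field_rates, use.names = FALSE))
  if (length(rates) && any(rates < 0 | rates > 1)) stopf("error rates must lie in [0, 1]")
  structure(list(future_date_rate = future_date_rate,
                 illogical_date_rate = illogical_date_rate,
                 implausible_value_rate = implausible_value_rate,
                 missing_field_rates = missing_field_rates,
                 missing_principal_rate = missing_principal_rate,
                 unmapped_rx_rate = unmapped_rx_rate,
                 missing_lab_unit_rate = missing_lab_unit_rate,
                 missing_loinc_rate = missing_loinc_rate,
                 duplicate_key_rate = duplicate_key_rate,
                 orphan_record_rate = orphan_record_rate),
            class = "error_profile")
}

#' Refresh-sequence scenario
#'
#' @param n_refreshes number of scheduled refreshes.
#' @param refresh_interval months between refreshes (quarterly by default).
#' @param events list of events, each a list with `ordinal`, `kind` (one of
#'   `feed_loss`, `feed_gain`, `quarter_gap`, `etl_change`,
#'   `no_submission`), `magnitude` (fraction in `[0,1]`), and optionally
#'   `tables` (affected tables), `backfill` (feed_gain: include the new
#'   feed's historical records), `months_back` (quarter_gap: how many months
#'   before the refresh the dropped quarter ends; default 6).
#' @return a `refresh_scenario` list.
#' @export
refresh_scenario <- function(n_refreshes, refresh_interval = 3, events = list()) {
  for (ev in events) {
    if (is.null(ev$ordinal) || ev$ordinal < 1 || ev$ordinal > n_refreshes) {
      stopf("event ordinal out of range [1, %d]", n_refreshes)
    }
    if (!ev$kind %in% c("feed_loss", "feed_gain", "quarter_gap", "etl_change",
                        "no_submission")) {
      stopf("unknown event kind '%s'", ev$kind)
    }
    mag <- ev$magnitude %||% 0
    if (mag < 0 || mag > 1) stopf("event magnitude must lie in [0, 1]")
  }
  structure(list(n_refreshes = as.integer(n_refreshes),
                 refresh_interval = as.integer(refresh_interval),
                 events = events),
            class = "refresh_scenario")
}

load_code_list <- function(name) {
  utils::read.csv(cdm_resource(name), colClasses = "character",
                  na.strings = character(0), check.names = FALSE)
}

# Shift a date by n months, preserving "last day of month" semantics.
shift_months_eom <- function(date, n) {
  nxt <- add_months(date, 1)
  if (as.integer(nxt - date) <= 31 && format(date + 1, "%d") == "01") {
    # date is a month end -> month end of the target month
    add_months(date, n + 1) - 1
  } else {
    day <- as.integer(format(date, "%d"))
    first <- add_months(date, n)
    last <- add_months(first, 1) - 1
    min(first + (day - 1), last)
  }
}

# Sample admit dates with a linear-growth + seasonal monthly trend.
sample_event_dates <- function(n, span, growth, amp) {
  if (n == 0) return(as.Date(character(0)))
  m0 <- month_index(span[1]); m1 <- month_index(span[2])
  months <- m0:m1
  tfrac <- if (length(months) > 1) (months - m0) / (m1 - m0) else 0
  w <- (1 + growth * tfrac) * (1 + amp * sin(2 * pi * (months %% 12L) / 12))
  mi <- sample(months, n, replace = TRUE, prob = w)
  starts <- as.Date(sprintf("%04d-%02d-01", mi %/% 12L, mi %% 12L + 1L))
  ends <- as.Date(vapply(starts, function(s) format(add_months(s, 1) - 1), ""))
  lo <- pmax(starts, span[1]); hi <- pmin(ends, span[2])
  lo + floor(stats::runif(n) * (as.integer(hi - lo) + 1L))
}

sample_codes_per_group <- function(counts, pool_n) {
  # index list: for each group i, `counts[i]` distinct indices into the pool
  lapply(counts, function(k) {
    if (k == 0) integer(0) else sample.int(pool_n, min(k, pool_n))
  })
}

empty_tables <- function(schema) {
  lapply(schema$tables, function(tb) {
    cols <- lapply(tb$fields, function(f) {
      switch(f$kind,
             date = , datetime = as.Date(character(0)),
             numeric = numeric(0),
             character(0))
    })
    names(cols) <- vapply(tb$fields, `[[`, "", "name")
    df <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
    df$.facility <- character(0)
    df
  })
}

# Clean (defect-free) full-span generation. Children are dated at their
# encounter's admit date; inpatient-type encounters get a discharge date and
# disposition; death dates follow the patient's last event.
generate_clean <- function(pop, schema, span = pop$date_range,
                           id_prefix = "", patid_offset = 0L) {
  n <- pop$n_patients
  tabs <- empty_tables(schema)
  if (n == 0) {
    return(list(tables = tabs))
  }

  dx_codes <- load_code_list("codes_dx.csv")
  px_codes <- load_code_list("codes_px.csv")
  loinc <- load_code_list("codes_loinc.csv")
  rxnorm <- load_code_list("codes_rxnorm.csv")
  rx_pref <- rxnorm[rxnorm$TTY %in% c("SCD", "SBD", "GPCK", "BPCK"), , drop = FALSE]

  patid <- sprintf("P%s%05d", id_prefix, patid_offset + seq_len(n))
  birth <- span[2] - 365L * 18L -
    floor(stats::runif(n) * (365.25 * 70))
  demo <- data.frame(
    PATID = patid,
    BIRTH_DATE = as.Date(birth, origin = "1970-01-01"),
    SEX = sample(c("F", "M", "OT", "UN"), n, TRUE, c(0.49, 0.49, 0.01, 0.01)),
    HISPANIC = sample(c("Y", "N", "UN"), n, TRUE, c(0.15, 0.80, 0.05)),
    RACE = sample(c("01", "02", "03", "04", "05", "06", "07", "OT", "UN"), n,
                  TRUE, c(0.01, 0.02, 0.12, 0.01, 0.65, 0.06, 0.05, 0.04, 0.04)),
    stringsAsFactors = FALSE)
  demo$.facility <- ""

  n_enc_per_pat <- stats::rpois(n, pop$encounters_per_patient)
  n_enc <- sum(n_enc_per_pat)
  enc <- NULL
  if (n_enc > 0) {
    enc_pat <- rep(patid, n_enc_per_pat)
    admit <- sample_event_dates(n_enc, span, pop$growth, pop$seasonal_amp)
    etype <- sample(names(pop$enc_type_mix), n_enc, TRUE, pop$enc_type_mix)
    fac <- sample(names(pop$facility_shares), n_enc, TRUE, pop$facility_shares)
    ip_like <- etype %in% c("IP", "EI", "IS")
    los <- ifelse(ip_like, stats::rpois(n_enc, 4) + 1L, 0L)
    discharge <- as.Date(ifelse(ip_like, admit + los, NA), origin = "1970-01-01")
    discharge <- pmin(discharge, span[2], na.rm = FALSE)
    dispo <- ifelse(ip_like,
                    sample(c("A", "E", "OT"), n_enc, TRUE, c(0.93, 0.04, 0.03)),
                    "")
    enc <- data.frame(
      ENCOUNTERID = sprintf("E%s%06d", id_prefix, seq_len(n_enc)),
      PATID = enc_pat, ADMIT_DATE = admit, DISCHARGE_DATE = discharge,
      ENC_TYPE = etype, FACILITYID = fac, DISCHARGE_DISPOSITION = dispo,
      stringsAsFactors = FALSE)
    enc$.facility <- fac
  }

  make_children <- function(counts, builder) {
    total <- sum(counts)
    if (total == 0 || is.null(enc)) return(NULL)
    idx <- rep(seq_len(nrow(enc)), counts)
    builder(idx, counts)
  }

  dx <- NULL; px <- NULL; lab <- NULL; rx <- NULL; vit <- NULL
  if (!is.null(enc)) {
    icd10 <- dx_codes[dx_codes$DX_TYPE == "10", , drop = FALSE]
    icd9 <- dx_codes[dx_codes$DX_TYPE == "09", , drop = FALSE]
    ndx <- stats::rpois(n_enc, pop$diagnoses_per_encounter)
    dx <- make_children(ndx, function(idx, counts) {
      codes10 <- sample_codes_per_group(counts, nrow(icd10))
      code_idx <- unlist(codes10)
      d <- data.frame(
        DIAGNOSISID = sprintf("D%s%07d", id_prefix, seq_along(idx)),
        PATID = enc$PATID[idx], ENCOUNTERID = enc$ENCOUNTERID[idx],
        DX = icd10$DX[code_idx], DX_TYPE = "10",
        DX_DATE = enc$ADMIT_DATE[idx],
        PDX = "S", stringsAsFactors = FALSE)
      # records dated before the ICD-10 transition carry ICD-9 codes
      pre10 <- d$DX_DATE < as.Date("2015-10-01")
      if (any(pre10)) {
        d$DX[pre10] <- sample(icd9$DX, sum(pre10), TRUE)
        d$DX_TYPE[pre10] <- "09"
      }
      # first diagnosis of an inpatient-type encounter is principal
      first_of_enc <- !duplicated(idx)
      ip_enc <- enc$ENC_TYPE[idx] %in% c("IP", "EI", "IS")
      d$PDX[first_of_enc & ip_enc] <- "P"
      d$.facility <- enc$.facility[idx]
      d
    })

    npx <- stats::rpois(n_enc, pop$procedures_per_encounter)
    px <- make_children(npx, function(idx, counts) {
      ch <- px_codes[px_codes$PX_TYPE == "CH", , drop = FALSE]
      code_idx <- unlist(sample_codes_per_group(counts, nrow(ch)))
      p <- data.frame(
        PROCEDURESID = sprintf("X%s%07d", id_prefix, seq_along(idx)),
        PATID = enc$PATID[idx], ENCOUNTERID = enc$ENCOUNTERID[idx],
        PX = ch$PX[code_idx], PX_TYPE = "CH",
        PX_DATE = enc$ADMIT_DATE[idx], stringsAsFactors = FALSE)
      p$.facility <- enc$.facility[idx]
      p
    })

    nlab <- stats::rpois(n_enc, pop$labs_per_encounter)
    lab <- make_children(nlab, function(idx, counts) {
      code_idx <- unlist(sample_codes_per_group(counts, nrow(loinc)))
      lo <- as.numeric(loinc$LOW[code_idx]); hi <- as.numeric(loinc$HIGH[code_idx])
      units <- vapply(strsplit(loinc$UNITS[code_idx], "|", fixed = TRUE),
                      function(u) u[sample.int(length(u), 1L)], "")
      l <- data.frame(
        LAB_RESULT_CM_ID = sprintf("L%s%07d", id_prefix, seq_along(idx)),
        PATID = enc$PATID[idx], ENCOUNTERID = enc$ENCOUNTERID[idx],
        LAB_LOINC = loinc$LAB_LOINC[code_idx],
        RESULT_DATE = enc$ADMIT_DATE[idx],
        RESULT_NUM = round(lo + stats::runif(length(idx)) * (hi - lo), 2),
        RESULT_UNIT = units, stringsAsFactors = FALSE)
      l$.facility <- enc$.facility[idx]
      l
    })

    nrx <- stats::rpois(n_enc, pop$prescriptions_per_encounter)
    rx <- make_children(nrx, function(idx, counts) {
      code_idx <- unlist(sample_codes_per_group(counts, nrow(rx_pref)))
      days <- sample(c(7, 14, 30, 90), length(idx), TRUE, c(0.2, 0.2, 0.4, 0.2))
      r <- data.frame(
        PRESCRIBINGID = sprintf("R%s%07d", id_prefix, seq_along(idx)),
        PATID = enc$PATID[idx], ENCOUNTERID = enc$ENCOUNTERID[idx],
        RX_ORDER_DATE = enc$ADMIT_DATE[idx],
        RXNORM_CUI = rx_pref$RXNORM_CUI[code_idx],
        RX_DAYS_SUPPLY = days,
        RX_QUANTITY = days * sample(1:2, length(idx), TRUE),
        stringsAsFactors = FALSE)
      r$.facility <- enc$.facility[idx]
      r
    })

    has_vital <- stats::runif(n_enc) < pop$vitals_per_encounter
    if (any(has_vital)) {
      idx <- which(has_vital)
      vit <- data.frame(
        VITALID = sprintf("V%s%07d", id_prefix, seq_along(idx)),
        PATID = enc$PATID[idx], ENCOUNTERID = enc$ENCOUNTERID[idx],
        MEASURE_DATE = enc$ADMIT_DATE[idx],
        HT = round(stats::runif(length(idx), 58, 76), 1),
        WT = round(stats::runif(length(idx), 100, 300), 1),
        SYSTOLIC = round(stats::runif(length(idx), 95, 165)),
        DIASTOLIC = round(stats::runif(length(idx), 55, 95)),
        stringsAsFactors = FALSE)
      vit$.facility <- enc$.facility[idx]
    }
  }

  death <- NULL
  n_death <- round(pop$death_rate * n)
  if (n_death > 0 && !is.null(enc)) {
    # deterministic count; death follows the patient's last recorded event
    dead <- sample(patid, n_death)
    last_event <- tapply(enc$ADMIT_DATE, enc$PATID, max)
    dd <- vapply(dead, function(p) {
      base <- if (p %in% names(last_event)) as.Date(last_event[[p]], origin = "1970-01-01") else span[1]
      format(min(base + sample.int(60L, 1L), span[2]))
    }, "")
    death <- data.frame(PATID = dead, DEATH_DATE = as.Date(dd),
                        DEATH_SOURCE = sample(c("L", "S", "T"), n_death, TRUE),
                        stringsAsFactors = FALSE)
    death$.facility <- ""
  }

  for (nm_tab in list(list("DEMOGRAPHIC", demo), list("ENCOUNTER", enc),
                      list("DIAGNOSIS", dx), list("PROCEDURES", px),
                      list("LAB_RESULT_CM", lab), list("PRESCRIBING", rx),
                      list("VITAL", vit), list("DEATH", death))) {
    if (!is.null(nm_tab[[2]])) tabs[[nm_tab[[1]]]] <- nm_tab[[2]]
  }
  list(tables = tabs)
}

# Snapshot of a full-span clean datamart as of `date`: keep records dated on
# or before `date`; clamp still-open discharges to the snapshot date.
snapshot_tables <- function(tabs, date, schema) {
  out <- tabs
  if (nrow(out$ENCOUNTER) > 0) {
    keep <- !is.na(out$ENCOUNTER$ADMIT_DATE) & out$ENCOUNTER$ADMIT_DATE <= date
    out$ENCOUNTER <- out$ENCOUNTER[keep, , drop = FALSE]
    out$ENCOUNTER$DISCHARGE_DATE <- pmin(out$ENCOUNTER$DISCHARGE_DATE, date)
  }
  for (tn in c("DIAGNOSIS", "PROCEDURES", "LAB_RESULT_CM", "PRESCRIBING", "VITAL")) {
    df <- schema$tables[[tn]]$date_field
    if (nrow(out[[tn]]) > 0) {
      keep <- !is.na(out[[tn]][[df]]) & out[[tn]][[df]] <= date
      out[[tn]] <- out[[tn]][keep, , drop = FALSE]
    }
  }
  if (nrow(out$DEATH) > 0) {
    out$DEATH <- out$DEATH[!is.na(out$DEATH$DEATH_DATE) &
                             out$DEATH$DEATH_DATE <= date, , drop = FALSE]
  }
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

audit_row <- function(table, key, field, defect) {
  data.frame(table = table, key = key, field = field, defect = defect,
             stringsAsFactors = FALSE)
}

# Inject defects into a snapshot; returns list(tables, audit).
inject_errors <- function(tabs, errors, refresh_date, schema, seed) {
  audit <- list()
  touched <- function(table) {
    keys <- unlist(lapply(audit, function(a) a$key[a$table == table]))
    unique(keys %||% character(0))
  }
  pick <- function(eligible_keys, rate) {
    if (length(eligible_keys) == 0 || rate <= 0) return(character(0))
    eligible_keys[stats::runif(length(eligible_keys)) < rate]
  }

  with_seed(seed, {
    enc <- tabs$ENCOUNTER

    # 1. future dates: shift the whole encounter bundle past the refresh
    # date; deceased patients excluded so the after-death rule stays clean
    if (errors$future_date_rate > 0 && nrow(enc) > 0) {
      dead <- if (nrow(tabs$DEATH) > 0) tabs$DEATH$PATID else character(0)
      sel <- pick(enc$ENCOUNTERID[!enc$PATID %in% dead], errors$future_date_rate)
      if (length(sel)) {
        i <- match(sel, enc$ENCOUNTERID)
        offset <- as.integer(refresh_date - enc$ADMIT_DATE[i]) +
          sample(30:365, length(i), TRUE)
        enc$ADMIT_DATE[i] <- enc$ADMIT_DATE[i] + offset
        audit[[length(audit) + 1L]] <- audit_row("ENCOUNTER", sel, "ADMIT_DATE", "future_date")
        has_dis <- !is.na(enc$DISCHARGE_DATE[i])
        if (any(has_dis)) {
          enc$DISCHARGE_DATE[i[has_dis]] <- enc$DISCHARGE_DATE[i[has_dis]] + offset[has_dis]
          audit[[length(audit) + 1L]] <-
            audit_row("ENCOUNTER", sel[has_dis], "DISCHARGE_DATE", "future_date")
        }
        for (tn in c("DIAGNOSIS", "PROCEDURES", "LAB_RESULT_CM", "PRESCRIBING", "VITAL")) {
          tb <- tabs[[tn]]
          if (nrow(tb) == 0) next
          df <- schema$tables[[tn]]$date_field
          j <- which(tb$ENCOUNTERID %in% sel)
          if (length(j)) {
            tb[[df]][j] <- enc$ADMIT_DATE[match(tb$ENCOUNTERID[j], enc$ENCOUNTERID)]
            pk <- schema$tables[[tn]]$primary_key
            audit[[length(audit) + 1L]] <- audit_row(tn, tb[[pk]][j], df, "future_date")
            tabs[[tn]] <- tb
          }
        }
      }
      tabs$ENCOUNTER <- enc
    }

    # 2. illogical dates: discharge before admit; procedures outside window
    if (errors$illogical_date_rate > 0) {
      if (nrow(enc) > 0) {
        elig <- enc$ENCOUNTERID[!is.na(enc$DISCHARGE_DATE) &
                                  !enc$ENCOUNTERID %in% touched("ENCOUNTER")]
        sel <- pick(elig, errors$illogical_date_rate)
        if (length(sel)) {
          i <- match(sel, enc$ENCOUNTERID)
          enc$DISCHARGE_DATE[i] <- enc$ADMIT_DATE[i] - sample(1:30, length(i), TRUE)
          audit[[length(audit) + 1L]] <-
            audit_row("ENCOUNTER", sel, "DISCHARGE_DATE", "illogical_date")
          tabs$ENCOUNTER <- enc
        }
      }
      px <- tabs$PROCEDURES
      if (nrow(px) > 0) {
        # skip procedures whose encounter already carries a date defect --
        # a shifted admit/discharge would move the window under the new date
        elig <- px$PROCEDURESID[!px$PROCEDURESID %in% touched("PROCEDURES") &
                                  !px$ENCOUNTERID %in% touched("ENCOUNTER") &
                                  px$ENCOUNTERID %in% enc$ENCOUNTERID]
        sel <- pick(elig, errors$illogical_date_rate)
        if (length(sel)) {
          i <- match(sel, px$PROCEDURESID)
          admit <- enc$ADMIT_DATE[match(px$ENCOUNTERID[i], enc$ENCOUNTERID)]
          px$PX_DATE[i] <- admit - 7L - sample(1:60, length(i), TRUE)
          audit[[length(audit) + 1L]] <- audit_row("PROCEDURES", sel, "PX_DATE", "illogical_date")
          tabs$PROCEDURES <- px
        }
      }
    }

    # 3. implausible values: systolic blood pressure far out of range
    vit <- tabs$VITAL
    if (errors$implausible_value_rate > 0 && nrow(vit) > 0) {
      elig <- vit$VITALID[!is.na(vit$SYSTOLIC) & !vit$VITALID %in% touched("VITAL")]
      sel <- pick(elig, errors$implausible_value_rate)
      if (length(sel)) {
        i <- match(sel, vit$VITALID)
        vit$SYSTOLIC[i] <- 400 + round(stats::runif(length(i)) * 100)
        audit[[length(audit) + 1L]] <- audit_row("VITAL", sel, "SYSTOLIC", "implausible_value")
        tabs$VITAL <- vit
      }
    }

    # 4. field-level missingness
    for (spec in names(errors$missing_field_rates)) {
      parts <- strsplit(spec, ".", fixed = TRUE)[[1]]
      tn <- parts[1]; fld <- parts[2]
      rate <- errors$missing_field_rates[[spec]]
      tb <- tabs[[tn]]
      if (is.null(tb) || nrow(tb) == 0 || rate <= 0) next
      pk <- schema$tables[[tn]]$primary_key
      elig <- tb[[pk]][!is_missing_value(tb[[fld]]) & !tb[[pk]] %in% touched(tn)]
      sel <- pick(elig, rate)
      if (length(sel)) {
        i <- match(sel, tb[[pk]])
        tb[[fld]][i] <- if (is.character(tb[[fld]])) "" else NA
        audit[[length(audit) + 1L]] <- audit_row(tn, sel, fld, "missing_value")
        tabs[[tn]] <- tb
      }
    }

    # 5. principal-diagnosis omission (encounter-level)
    dx <- tabs$DIAGNOSIS
    if (errors$missing_principal_rate > 0 && nrow(dx) > 0) {
      with_p <- unique(dx$ENCOUNTERID[dx$PDX == "P"])
      elig <- setdiff(with_p, touched("ENCOUNTER"))
      sel <- pick(elig, errors$missing_principal_rate)
      if (length(sel)) {
        j <- which(dx$ENCOUNTERID %in% sel & dx$PDX == "P")
        dx$PDX[j] <- "S"
        audit[[length(audit) + 1L]] <- audit_row("ENCOUNTER", sel, "PDX", "missing_principal")
        tabs$DIAGNOSIS <- dx
      }
    }

    # 6. RxNorm codes outside the preferred term types (or absent)
    rx <- tabs$PRESCRIBING
    if (errors$unmapped_rx_rate > 0 && nrow(rx) > 0) {
      rxnorm <- load_code_list("codes_rxnorm.csv")
      ing <- rxnorm$RXNORM_CUI[rxnorm$TTY == "IN"]
      elig <- rx$PRESCRIBINGID[!rx$PRESCRIBINGID %in% touched("PRESCRIBING")]
      sel <- pick(elig, errors$unmapped_rx_rate)
      if (length(sel)) {
        i <- match(sel, rx$PRESCRIBINGID)
        blank <- stats::runif(length(i)) < 1 / 3
        rx$RXNORM_CUI[i] <- ifelse(blank, "", sample(ing, length(i), TRUE))
        audit[[length(audit) + 1L]] <- audit_row("PRESCRIBING", sel, "RXNORM_CUI", "unmapped_rx")
        tabs$PRESCRIBING <- rx
      }
    }

    # 7/8. lab LOINC and unit completeness
    lab <- tabs$LAB_RESULT_CM
    if (errors$missing_loinc_rate > 0 && nrow(lab) > 0) {
      elig <- lab$LAB_RESULT_CM_ID[!is.na(lab$RESULT_NUM) &
                                     !is_missing_value(lab$LAB_LOINC) &
                                     !lab$LAB_RESULT_CM_ID %in% touched("LAB_RESULT_CM")]
      sel <- pick(elig, errors$missing_loinc_rate)
      if (length(sel)) {
        lab$LAB_LOINC[match(sel, lab$LAB_RESULT_CM_ID)] <- ""
        audit[[length(audit) + 1L]] <- audit_row("LAB_RESULT_CM", sel, "LAB_LOINC", "missing_loinc")
        tabs$LAB_RESULT_CM <- lab
      }
    }
    lab <- tabs$LAB_RESULT_CM
    if (errors$missing_lab_unit_rate > 0 && nrow(lab) > 0) {
      elig <- lab$LAB_RESULT_CM_ID[!is.na(lab$RESULT_NUM) &
                                     !is_missing_value(lab$RESULT_UNIT) &
                                     !lab$LAB_RESULT_CM_ID %in% touched("LAB_RESULT_CM")]
      sel <- pick(elig, errors$missing_lab_unit_rate)
      if (length(sel)) {
        lab$RESULT_UNIT[match(sel, lab$LAB_RESULT_CM_ID)] <- ""
        audit[[length(audit) + 1L]] <-
          audit_row("LAB_RESULT_CM", sel, "RESULT_UNIT", "missing_lab_unit")
        tabs$LAB_RESULT_CM <- lab
      }
    }

    # 9. duplicate primary keys (clean encounter rows copied verbatim)
    enc <- tabs$ENCOUNTER
    if (errors$duplicate_key_rate > 0 && nrow(enc) > 0) {
      elig <- enc$ENCOUNTERID[!enc$ENCOUNTERID %in% touched("ENCOUNTER")]
      sel <- pick(elig, errors$duplicate_key_rate)
      if (length(sel)) {
        tabs$ENCOUNTER <- rbind(enc, enc[match(sel, enc$ENCOUNTERID), , drop = FALSE])
        rownames(tabs$ENCOUNTER) <- NULL
        audit[[length(audit) + 1L]] <-
          audit_row("ENCOUNTER", sel, "ENCOUNTERID", "duplicate_key")
      }
    }

    # 10. orphan records: diagnoses pointed at nonexistent encounters
    dx <- tabs$DIAGNOSIS
    if (errors$orphan_record_rate > 0 && nrow(dx) > 0) {
      # principal-flagged rows excluded: unlinking one would silently strip
      # its encounter's principal diagnosis and break that check's oracle
      elig <- dx$DIAGNOSISID[!dx$DIAGNOSISID %in% touched("DIAGNOSIS") &
                               !dx$ENCOUNTERID %in% touched("ENCOUNTER") &
                               dx$PDX != "P"]
      sel <- pick(elig, errors$orphan_record_rate)
      if (length(sel)) {
        i <- match(sel, dx$DIAGNOSISID)
        dx$ENCOUNTERID[i] <- sprintf("EORPHAN%05d", seq_along(i))
        audit[[length(audit) + 1L]] <- audit_row("DIAGNOSIS", sel, "ENCOUNTERID", "orphan_record")
        tabs$DIAGNOSIS <- dx
      }
    }
  })

  audit_df <- rbind_all(audit) %||% audit_row("x", "x", "x", "x")[0, ]
  list(tables = tabs, audit = audit_df)
}

#' Generate one synthetic DataMart refresh
#'
#' Generates a clean, CDM-conformant DataMart from `pop`, then injects the
#' defect modes of `errors`, logging every injected defect in the returned
#' refresh's `$audit` (columns `table`, `key`, `field`, `defect`). The
#' result is fully deterministic given `pop$seed`.
#'
#' @param pop a [population_config()].
#' @param errors an [error_profile()].
#' @param schema a `cdm_schema` (packaged default schema if omitted).
#' @param datamart_id DataMart identifier.
#' @param refresh_date date of the refresh; defaults to the end of
#'   `pop$date_range`.
#' @param refresh_ordinal ordinal of this refresh.
#' @return a `datamart_refresh` with an attached defect audit log.
#' @export
#' @examples
#' r <- generate_datamart(population_config(n_patients = 20))
#' nrow(r$tables$ENCOUNTER)
generate_datamart <- function(pop, errors = error_profile(),
                              schema = load_schema(), datamart_id = "DM01",
                              refresh_date = pop$date_range[2],
                              refresh_ordinal = 1L) {
  core <- c("DEMOGRAPHIC", "ENCOUNTER", "DIAGNOSIS", "PROCEDURES",
            "PRESCRIBING", "LAB_RESULT_CM", "VITAL", "DEATH")
  if (!all(core %in% names(schema$tables))) {
    stopf("configuration error: the synthetic generator needs the %d core tables; schema lacks %s",
          length(core), paste(setdiff(core, names(schema$tables)), collapse = ", "))
  }
  clean <- with_seed(pop$seed, generate_clean(pop, schema))
  tabs <- snapshot_tables(clean$tables, refresh_date, schema)
  inj <- inject_errors(tabs, errors, refresh_date, schema,
                       seed = (pop$seed + 104729L) %% .Machine$integer.max)
  new_refresh(datamart_id, refresh_date, refresh_ordinal, inj$tables,
              audit = inj$audit)
}

subset_sum_facilities <- function(shares, target) {
  # pick the facility subset whose combined record share is closest to target
  nms <- names(shares)
  best <- NULL; best_err <- Inf
  for (mask in seq_len(2^length(shares) - 1)) {
    sel <- nms[bitwAnd(mask, 2^(seq_along(shares) - 1)) > 0]
    err <- abs(sum(shares[sel]) - target)
    if (err < best_err) { best <- sel; best_err <- err }
  }
  best
}

drop_facilities <- function(tabs, facilities) {
  lapply(tabs, function(tb) {
    if (nrow(tb) == 0 || is.null(tb$.facility)) return(tb)
    out <- tb[!tb$.facility %in% facilities, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate a sequence of refreshes for one DataMart
#'
#' Refresh k+1 extends refresh k by one refresh interval of newly accrued
#' records. Scenario events perturb individual refreshes: `feed_loss`
#' permanently drops the facilities closest in combined share to the stated
#' magnitude; `feed_gain` onboards a new facility (forward-only unless
#' `backfill = TRUE`); `quarter_gap` drops one calendar quarter of records
#' from a single refresh; `etl_change` drops a random fraction of rows of
#' the affected tables from that refresh onward; `no_submission` omits the
#' refresh from the history entirely.
#'
#' @param pop a [population_config()]; its `date_range` spans the data of
#'   the first refresh, whose refresh date is the end of the range.
#' @param errors an [error_profile()] applied to every submitted refresh.
#' @param scenario a [refresh_scenario()].
#' @param schema a `cdm_schema`.
#' @param datamart_id DataMart identifier.
#' @return a `refresh_history`.
#' @export
generate_refresh_sequence <- function(pop, errors = error_profile(),
                                      scenario, schema = load_schema(),
                                      datamart_id = "DM01") {
  n_ref <- scenario$n_refreshes
  refresh_dates <- as.Date(vapply(seq_len(n_ref), function(k) {
    format(shift_months_eom(pop$date_range[2], (k - 1) * scenario$refresh_interval))
  }, ""))
  span <- c(pop$date_range[1], refresh_dates[n_ref])

  pop_full <- pop
  pop_full$date_range <- span
  clean <- with_seed(pop$seed, generate_clean(pop_full, schema))

  events_at <- function(kind) Filter(function(e) e$kind == kind, scenario$events)

  # feed-gain cohorts generated up front so later refreshes accumulate them
  gains <- list()
  for (ev in events_at("feed_gain")) {
    gain_pop <- pop_full
    gain_pop$n_patients <- max(1L, round((ev$magnitude %||% 0.1) * pop$n_patients))
    gain_start <- if (isTRUE(ev$backfill)) span[1] else
      shift_months_eom(refresh_dates[ev$ordinal], -scenario$refresh_interval) + 1
    gain_pop$date_range <- c(gain_start, span[2])
    gain_pop$facility_shares <- stats::setNames(1, sprintf("FACGAIN%d", ev$ordinal))
    g <- with_seed(pop$seed + 31L * ev$ordinal,
                   generate_clean(gain_pop, schema, span = gain_pop$date_range,
                                  id_prefix = sprintf("G%d", ev$ordinal),
                                  patid_offset = 0L))
    gains[[length(gains) + 1L]] <- list(ordinal = ev$ordinal, tables = g$tables)
  }

  # etl_change: choose dropped row keys once, applied from the ordinal onward
  etl_drops <- list()
  for (ev in events_at("etl_change")) {
    affected <- ev$tables %||% "DIAGNOSIS"
    for (tn in affected) {
      tb <- clean$tables[[tn]]
      pk <- schema$tables[[tn]]$primary_key
      keys <- with_seed(pop$seed + 97L * ev$ordinal,
                        tb[[pk]][stats::runif(nrow(tb)) < (ev$magnitude %||% 0)])
      etl_drops[[length(etl_drops) + 1L]] <-
        list(ordinal = ev$ordinal, table = tn, keys = keys)
    }
  }

  lost_facilities <- character(0)
  refreshes <- list()
  skip <- vapply(events_at("no_submission"), `[[`, 0, "ordinal")

  for (k in seq_len(n_ref)) {
    for (ev in events_at("feed_loss")) {
      if (ev$ordinal == k) {
        lost_facilities <- union(lost_facilities,
                                 subset_sum_facilities(pop$facility_shares,
                                                       ev$magnitude %||% 0))
      }
    }
    if (k %in% skip) next

    tabs <- clean$tables
    for (g in gains) {
      if (k >= g$ordinal) {
        for (tn in names(tabs)) {
          if (nrow(g$tables[[tn]]) > 0) {
            tabs[[tn]] <- rbind(tabs[[tn]], g$tables[[tn]])
          }
        }
      }
    }
    tabs <- snapshot_tables(tabs, refresh_dates[k], schema)
    tabs <- drop_facilities(tabs, lost_facilities)
    for (ed in etl_drops) {
      if (k >= ed$ordinal) {
        pk <- schema$tables[[ed$table]]$primary_key
        tb <- tabs[[ed$table]]
        tabs[[ed$table]] <- tb[!tb[[pk]] %in% ed$keys, , drop = FALSE]
      }
    }
    for (ev in events_at("quarter_gap")) {
      if (ev$ordinal == k) {
        mb <- ev$months_back %||% 6
        gap_end <- month_index(refresh_dates[k]) - mb
        gap_months <- (gap_end - 2):gap_end
        for (tn in names(tabs)) {
          df <- schema$tables[[tn]]$date_field
          if (is.null(df) || is.na(df) || nrow(tabs[[tn]]) == 0) next
          mi <- month_index(tabs[[tn]][[df]])
          keep <- is.na(mi) | !mi %in% gap_months
          tabs[[tn]] <- tabs[[tn]][keep, , drop = FALSE]
        }
      }
    }
    inj <- inject_errors(tabs, errors, refresh_dates[k], schema,
                         seed = (pop$seed + 7919L * k) %% .Machine$integer.max)
    refreshes[[length(refreshes) + 1L]] <-
      new_refresh(datamart_id, refresh_dates[k], k, inj$tables, audit = inj$audit)
  }
  new_refresh_history(refreshes)
}
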