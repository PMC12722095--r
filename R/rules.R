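# checks_catalog rules: the concrete numerator/denominator (or metric)
# logic for every check family, registered by rule name. Catalog checks
# bind a rule to parameters, a threshold and a classification.
#
# Boundary conventions: "future" means strictly after the refresh date;
# plausible ranges and encounter-date windows are closed intervals; a
# monthly count exactly at 50% of the preceding median still counts as
# complete for latency.

.check_rules <- new.env(parent = emptyenv())

define_rule <- function(name, expand, evaluate) {
  assign(name, list(expand = expand, evaluate = evaluate), envir = .check_rules)
}

rule_exists <- function(name) exists(name, envir = .check_rules, inherits = FALSE)

rule_expand <- function(check, schema) {
  get(check$rule, envir = .check_rules)$expand(check, schema)
}

rule_evaluate <- function(check, refresh, history, schema, years) {
  get(check$rule, envir = .check_rules)$evaluate(check, refresh, history,
                                                 schema, years)
}

mrow <- function(table, field = NA_character_, qualifier = NA_character_,
                 numerator = NA_real_, denominator = NA_real_,
                 value = NA_real_) {
  data.frame(table = table, field = field, qualifier = qualifier,
             numerator = as.numeric(numerator),
             denominator = as.numeric(denominator),
             value = as.numeric(value), stringsAsFactors = FALSE)
}

mexpand <- function(table, field = NA_character_, qualifier = NA_character_) {
  data.frame(table = table, field = field, qualifier = qualifier,
             stringsAsFactors = FALSE)
}

tab_or_null <- function(refresh, table) refresh$tables[[table]]

# ---- conformance ----------------------------------------------------------

define_rule("required_tables_present",
  expand = function(check, schema) mexpand(schema$required_tables),
  evaluate = function(check, refresh, history, schema, years) {
    rbind_all(lapply(schema$required_tables, function(tn) {
      mrow(tn, numerator = as.integer(is.null(refresh$tables[[tn]])),
           denominator = 1)
    }))
  })

define_rule("required_fields_present",
  expand = function(check, schema) {
    rows <- list()
    for (tb in schema$tables) {
      for (f in tb$fields) {
        if (f$required) rows[[length(rows) + 1L]] <- mexpand(tb$name, f$name)
      }
    }
    rbind_all(rows)
  },
  evaluate = function(check, refresh, history, schema, years) {
    rows <- list()
    for (tb in schema$tables) {
      tab <- tab_or_null(refresh, tb$name)
      for (f in tb$fields) {
        if (!f$required) next
        rows[[length(rows) + 1L]] <- if (is.null(tab)) {
          mrow(tb$name, f$name)                       # table absent: n/a
        } else {
          mrow(tb$name, f$name,
               numerator = as.integer(!f$name %in% names(tab)), denominator = 1)
        }
      }
    }
    rbind_all(rows)
  })

define_rule("datatype_conformance",
  expand = function(check, schema) {
    k <- schema_fields_of_kind(schema, c("date", "datetime", "numeric"))
    mexpand(k$table, k$field)
  },
  evaluate = function(check, refresh, history, schema, years) {
    pe <- refresh$parse_errors
    k <- schema_fields_of_kind(schema, c("date", "datetime", "numeric"))
    rbind_all(lapply(seq_len(nrow(k)), function(i) {
      tab <- tab_or_null(refresh, k$table[i])
      if (is.null(tab) || !k$field[i] %in% names(tab)) return(mrow(k$table[i], k$field[i]))
      n_bad <- if (is.null(pe)) 0L else sum(pe$table == k$table[i] & pe$field == k$field[i])
      n_ok <- sum(!is.na(tab[[k$field[i]]]))
      mrow(k$table[i], k$field[i], numerator = n_bad, denominator = n_ok + n_bad)
    }))
  })

define_rule("valueset_conformance",
  expand = function(check, schema) {
    k <- schema_fields_of_kind(schema, "coded")
    mexpand(k$table, k$field)
  },
  evaluate = function(check, refresh, history, schema, years) {
    k <- schema_fields_of_kind(schema, "coded")
    rbind_all(lapply(seq_len(nrow(k)), function(i) {
      tab <- tab_or_null(refresh, k$table[i])
      if (is.null(tab) || !k$field[i] %in% names(tab)) return(mrow(k$table[i], k$field[i]))
      f <- schema_field(schema, k$table[i], k$field[i])
      x <- tab[[k$field[i]]]
      present <- !is_missing_value(x)
      codes <- schema$value_sets[[f$value_set]]$codes
      mrow(k$table[i], k$field[i],
           numerator = sum(present & !x %in% codes), denominator = sum(present))
    }))
  })

define_rule("pk_uniqueness",
  expand = function(check, schema) mexpand(names(schema$tables)),
  evaluate = function(check, refresh, history, schema, years) {
    rbind_all(lapply(names(schema$tables), function(tn) {
      tab <- tab_or_null(refresh, tn)
      pk <- schema$tables[[tn]]$primary_key
      if (is.null(tab) || !pk %in% names(tab)) return(mrow(tn, pk))
      mrow(tn, pk, numerator = nrow(tab) - length(unique(tab[[pk]])),
           denominator = nrow(tab))
    }))
  })

define_rule("fk_integrity",
  expand = function(check, schema) {
    rows <- list()
    for (tb in schema$tables) {
      for (f in tb$fields) {
        if (!is.na(f$ref_table)) rows[[length(rows) + 1L]] <- mexpand(tb$name, f$name)
      }
    }
    rbind_all(rows)
  },
  evaluate = function(check, refresh, history, schema, years) {
    rows <- list()
    for (tb in schema$tables) {
      tab <- tab_or_null(refresh, tb$name)
      for (f in tb$fields) {
        if (is.na(f$ref_table)) next
        if (is.null(tab) || !f$name %in% names(tab)) {
          rows[[length(rows) + 1L]] <- mrow(tb$name, f$name)
          next
        }
        ref <- tab_or_null(refresh, f$ref_table)
        x <- tab[[f$name]]
        present <- !is_missing_value(x)
        valid <- if (is.null(ref) || !f$ref_field %in% names(ref)) character(0)
                 else ref[[f$ref_field]]
        rows[[length(rows) + 1L]] <- mrow(
          tb$name, f$name, qualifier = sprintf("-> %s.%s", f$ref_table, f$ref_field),
          numerator = sum(present & !x %in% valid), denominator = sum(present))
      }
    }
    rbind_all(rows)
  })

# ---- plausibility ---------------------------------------------------------

date_fields_for_future <- function(schema) {
  k <- schema_fields_of_kind(schema, c("date", "datetime"))
  k[k$field != "BIRTH_DATE", , drop = FALSE]   # future births: implausible-age rule
}

define_rule("future_dates",
  expand = function(check, schema) {
    k <- date_fields_for_future(schema)
    mexpand(k$table, k$field)
  },
  evaluate = function(check, refresh, history, schema, years) {
    k <- date_fields_for_future(schema)
    rbind_all(lapply(seq_len(nrow(k)), function(i) {
      tab <- tab_or_null(refresh, k$table[i])
      if (is.null(tab) || !k$field[i] %in% names(tab)) return(mrow(k$table[i], k$field[i]))
      d <- tab[[k$field[i]]]
      present <- !is.na(d)
      mrow(k$table[i], k$field[i],
           numerator = sum(present & d > refresh$refresh_date),
           denominator = sum(present))
    }))
  })

# encounter date window for linked records: closed interval
# [min(admit, discharge) - W, max(admit, discharge) + W]
encounter_window <- function(enc, window_days) {
  lo_raw <- pmin(enc$ADMIT_DATE, enc$DISCHARGE_DATE, na.rm = TRUE)
  hi_raw <- pmax(enc$ADMIT_DATE, enc$DISCHARGE_DATE, na.rm = TRUE)
  list(lo = lo_raw - window_days, hi = hi_raw + window_days)
}

define_rule("illogical_dates",
  expand = function(check, schema) {
    rbind_all(list(mexpand("ENCOUNTER", "DISCHARGE_DATE", "discharge-before-admit"),
                   mexpand("DEATH", "DEATH_DATE", "death-before-birth"),
                   mexpand("DIAGNOSIS", "DX_DATE", "outside-encounter-window"),
                   mexpand("PROCEDURES", "PX_DATE", "outside-encounter-window")))
  },
  evaluate = function(check, refresh, history, schema, years) {
    w <- check$params$window_days %||% 7
    rows <- list()
    enc <- tab_or_null(refresh, "ENCOUNTER")
    if (is.null(enc)) {
      rows[[1]] <- mrow("ENCOUNTER", "DISCHARGE_DATE", "discharge-before-admit")
    } else {
      both <- !is.na(enc$ADMIT_DATE) & !is.na(enc$DISCHARGE_DATE)
      rows[[1]] <- mrow("ENCOUNTER", "DISCHARGE_DATE", "discharge-before-admit",
                        numerator = sum(both & enc$DISCHARGE_DATE < enc$ADMIT_DATE),
                        denominator = sum(both))
    }
    death <- tab_or_null(refresh, "DEATH")
    demo <- tab_or_null(refresh, "DEMOGRAPHIC")
    if (is.null(death) || is.null(demo)) {
      rows[[2]] <- mrow("DEATH", "DEATH_DATE", "death-before-birth")
    } else {
      birth <- demo$BIRTH_DATE[match(death$PATID, demo$PATID)]
      both <- !is.na(death$DEATH_DATE) & !is.na(birth)
      rows[[2]] <- mrow("DEATH", "DEATH_DATE", "death-before-birth",
                        numerator = sum(both & death$DEATH_DATE < birth),
                        denominator = sum(both))
    }
    for (spec in list(c("DIAGNOSIS", "DX_DATE"), c("PROCEDURES", "PX_DATE"))) {
      tab <- tab_or_null(refresh, spec[1])
      if (is.null(tab) || is.null(enc)) {
        rows[[length(rows) + 1L]] <- mrow(spec[1], spec[2], "outside-encounter-window")
        next
      }
      i <- match(tab$ENCOUNTERID, enc$ENCOUNTERID)
      linked <- !is.na(i) & !is.na(tab[[spec[2]]]) & !is.na(enc$ADMIT_DATE[i])
      win <- encounter_window(enc[i[linked], , drop = FALSE], w)
      d <- tab[[spec[2]]][linked]
      rows[[length(rows) + 1L]] <- mrow(
        spec[1], spec[2], "outside-encounter-window",
        numerator = sum(d < win$lo | d > win$hi), denominator = sum(linked))
    }
    rbind_all(rows)
  })

outlier_ranges <- function(check) {
  ranges <- check$params$ranges %||% list()
  rbind_all(lapply(ranges, function(r) {
    data.frame(table = r$table, field = r$field, low = as.numeric(r$low),
               high = as.numeric(r$high), stringsAsFactors = FALSE)
  }))
}

define_rule("value_outliers",
  expand = function(check, schema) {
    r <- outlier_ranges(check)
    mexpand(r$table, r$field)
  },
  evaluate = function(check, refresh, history, schema, years) {
    r <- outlier_ranges(check)
    rbind_all(lapply(seq_len(nrow(r)), function(i) {
      tab <- tab_or_null(refresh, r$table[i])
      if (is.null(tab) || !r$field[i] %in% names(tab)) return(mrow(r$table[i], r$field[i]))
      x <- tab[[r$field[i]]]
      present <- !is.na(x)
      # closed plausible interval: values exactly at a bound are inside
      mrow(r$table[i], r$field[i],
           qualifier = sprintf("[%g, %g]", r$low[i], r$high[i]),
           numerator = sum(present & (x < r$low[i] | x > r$high[i])),
           denominator = sum(present))
    }))
  })

define_rule("ratio_band",
  expand = function(check, schema) {
    mode <- check$params$mode
    if (identical(mode, "dx_per_encounter") && isTRUE(check$params$stratify)) {
      codes <- schema$value_sets$ENC_TYPE$codes
      rbind_all(c(list(mexpand("DIAGNOSIS", qualifier = "overall")),
                  lapply(codes, function(ct) mexpand("DIAGNOSIS", qualifier = ct))))
    } else {
      tab <- switch(mode, encounters_per_visit = "ENCOUNTER",
                    dx_per_encounter = "DIAGNOSIS", px_per_encounter = "PROCEDURES")
      mexpand(tab, qualifier = "overall")
    }
  },
  evaluate = function(check, refresh, history, schema, years) {
    mode <- check$params$mode
    enc <- tab_or_null(refresh, "ENCOUNTER")
    if (mode == "encounters_per_visit") {
      if (is.null(enc) || nrow(enc) == 0) return(mrow("ENCOUNTER", qualifier = "overall"))
      key <- paste(enc$PATID, enc$ADMIT_DATE, enc$ENC_TYPE,
                   enc$FACILITYID %||% "", sep = "|")
      return(mrow("ENCOUNTER", qualifier = "overall",
                  value = nrow(enc) / length(unique(key))))
    }
    child_name <- if (mode == "dx_per_encounter") "DIAGNOSIS" else "PROCEDURES"
    child <- tab_or_null(refresh, child_name)
    if (is.null(enc) || nrow(enc) == 0 || is.null(child)) {
      return(mrow(child_name, qualifier = "overall"))
    }
    ratio_for <- function(enc_sub) {
      if (nrow(enc_sub) == 0) return(NA_real_)
      n_child <- sum(child$ENCOUNTERID %in% enc_sub$ENCOUNTERID)
      n_child / nrow(enc_sub)
    }
    rows <- list(mrow(child_name, qualifier = "overall", value = ratio_for(enc)))
    if (isTRUE(check$params$stratify)) {
      for (ct in schema$value_sets$ENC_TYPE$codes) {
        rows[[length(rows) + 1L]] <- mrow(
          child_name, qualifier = ct,
          value = ratio_for(enc[enc$ENC_TYPE == ct, , drop = FALSE]))
      }
    }
    rbind_all(rows)
  })

define_rule("principal_dx",
  expand = function(check, schema) mexpand("ENCOUNTER", "PDX"),
  evaluate = function(check, refresh, history, schema, years) {
    ip_types <- unlist(check$params$ip_types %||% c("IP", "EI", "IS"))
    enc <- tab_or_null(refresh, "ENCOUNTER")
    dx <- tab_or_null(refresh, "DIAGNOSIS")
    if (is.null(enc) || is.null(dx)) return(mrow("ENCOUNTER", "PDX"))
    ip <- enc$ENCOUNTERID[enc$ENC_TYPE %in% ip_types]
    with_dx <- intersect(ip, dx$ENCOUNTERID)
    with_p <- unique(dx$ENCOUNTERID[dx$PDX == "P"])
    mrow("ENCOUNTER", "PDX", qualifier = paste(ip_types, collapse = "/"),
         numerator = length(setdiff(with_dx, with_p)),
         denominator = length(with_dx))
  })

# DC2.08 detector: baseline for month m is the median of the surrounding
# +/-6 in-series months (excluding m); m is flagged when its count falls
# below alpha x baseline or above beta x baseline. The most recent 3 months
# are not evaluated (data may still be accruing at extraction).
flag_volume_outliers <- function(counts, alpha, beta, skip_recent = 3L) {
  n <- length(counts)
  evaluable <- seq_len(max(0L, n - skip_recent))
  flagged <- logical(length(evaluable))
  for (m in evaluable) {
    nbh <- setdiff(max(1L, m - 6L):min(n, m + 6L), m)
    baseline <- stats::median(counts[nbh])
    flagged[m] <- counts[m] < alpha * baseline || counts[m] > beta * baseline
  }
  list(evaluated = length(evaluable), flagged = sum(flagged),
       months = which(flagged))
}

define_rule("monthly_volume_outliers",
  expand = function(check, schema) {
    mexpand(unlist(check$params$tables %||% "ENCOUNTER"))
  },
  evaluate = function(check, refresh, history, schema, years) {
    alpha <- check$params$alpha %||% 0.25
    beta <- check$params$beta %||% 4.0
    rbind_all(lapply(unlist(check$params$tables %||% "ENCOUNTER"), function(tn) {
      if (is.null(tab_or_null(refresh, tn))) return(mrow(tn))
      vs <- volume_series(refresh, schema, tn, years)
      if (length(vs$counts) < 13) return(mrow(tn))   # too short: n/a
      fl <- flag_volume_outliers(vs$counts, alpha, beta)
      mrow(tn, qualifier = "monthly", numerator = fl$flagged,
           denominator = fl$evaluated)
    }))
  })

define_rule("implausible_age",
  expand = function(check, schema) mexpand("DEMOGRAPHIC", "BIRTH_DATE"),
  evaluate = function(check, refresh, history, schema, years) {
    max_age <- check$params$max_age %||% 115
    demo <- tab_or_null(refresh, "DEMOGRAPHIC")
    if (is.null(demo)) return(mrow("DEMOGRAPHIC", "BIRTH_DATE"))
    b <- demo$BIRTH_DATE
    present <- !is.na(b)
    age <- as.numeric(refresh$refresh_date - b) / 365.25
    mrow("DEMOGRAPHIC", "BIRTH_DATE",
         numerator = sum(present & (b > refresh$refresh_date | age > max_age)),
         denominator = sum(present))
  })

define_rule("events_after_death",
  expand = function(check, schema) mexpand("ENCOUNTER", "ADMIT_DATE", "after-death"),
  evaluate = function(check, refresh, history, schema, years) {
    grace <- check$params$grace_days %||% 30
    death <- tab_or_null(refresh, "DEATH")
    enc <- tab_or_null(refresh, "ENCOUNTER")
    if (is.null(death) || is.null(enc)) return(mrow("ENCOUNTER", "ADMIT_DATE", "after-death"))
    dd <- death$DEATH_DATE[match(enc$PATID, death$PATID)]
    scope <- !is.na(dd) & !is.na(enc$ADMIT_DATE)
    mrow("ENCOUNTER", "ADMIT_DATE", "after-death",
         numerator = sum(scope & enc$ADMIT_DATE > dd + grace),
         denominator = sum(scope))
  })

define_rule("nonnegative_values",
  expand = function(check, schema) {
    f <- check$params$fields
    rbind_all(lapply(f, function(x) mexpand(x$table, x$field)))
  },
  evaluate = function(check, refresh, history, schema, years) {
    rbind_all(lapply(check$params$fields, function(x) {
      tab <- tab_or_null(refresh, x$table)
      if (is.null(tab) || !x$field %in% names(tab)) return(mrow(x$table, x$field))
      v <- tab[[x$field]]
      present <- !is.na(v)
      mrow(x$table, x$field, numerator = sum(present & v < 0),
           denominator = sum(present))
    }))
  })

define_rule("duplicate_rows",
  expand = function(check, schema) {
    mexpand(unlist(check$params$tables %||% names(schema$tables)))
  },
  evaluate = function(check, refresh, history, schema, years) {
    rbind_all(lapply(unlist(check$params$tables %||% names(schema$tables)), function(tn) {
      tab <- tab_or_null(refresh, tn)
      if (is.null(tab)) return(mrow(tn))
      vis <- visible_columns(tab)
      mrow(tn, numerator = sum(duplicated(vis)), denominator = nrow(vis))
    }))
  })

# ---- completeness ---------------------------------------------------------

missingness_fields <- function(check) check$params$fields %||% list()

scope_rows <- function(tab, scope) {
  if (is.null(scope)) return(rep(TRUE, nrow(tab)))
  tab[[scope$field]] %in% unlist(scope$values)
}

define_rule("missingness",
  expand = function(check, schema) {
    rbind_all(lapply(missingness_fields(check), function(f) {
      q <- if (!is.null(f$scope)) {
        sprintf("%s in %s", f$scope$field, paste(unlist(f$scope$values), collapse = "/"))
      } else NA_character_
      mexpand(f$table, f$field, q)
    }))
  },
  evaluate = function(check, refresh, history, schema, years) {
    rbind_all(lapply(missingness_fields(check), function(f) {
      q <- if (!is.null(f$scope)) {
        sprintf("%s in %s", f$scope$field, paste(unlist(f$scope$values), collapse = "/"))
      } else NA_character_
      tab <- tab_or_null(refresh, f$table)
      if (is.null(tab) || !f$field %in% names(tab)) return(mrow(f$table, f$field, q))
      in_scope <- scope_rows(tab, f$scope)
      x <- tab[[f$field]][in_scope]
      mrow(f$table, f$field, q, numerator = sum(is_missing_value(x)),
           denominator = length(x))
    }))
  })

define_rule("patients_with_encounter",
  expand = function(check, schema) mexpand("DEMOGRAPHIC", "PATID"),
  evaluate = function(check, refresh, history, schema, years) {
    demo <- tab_or_null(refresh, "DEMOGRAPHIC")
    enc <- tab_or_null(refresh, "ENCOUNTER")
    if (is.null(demo)) return(mrow("DEMOGRAPHIC", "PATID"))
    with_enc <- if (is.null(enc)) character(0) else unique(enc$PATID)
    mrow("DEMOGRAPHIC", "PATID",
         numerator = sum(!demo$PATID %in% with_enc), denominator = nrow(demo))
  })

define_rule("encounters_with_diagnosis",
  expand = function(check, schema) mexpand("ENCOUNTER", "ENCOUNTERID"),
  evaluate = function(check, refresh, history, schema, years) {
    enc <- tab_or_null(refresh, "ENCOUNTER")
    dx <- tab_or_null(refresh, "DIAGNOSIS")
    if (is.null(enc)) return(mrow("ENCOUNTER", "ENCOUNTERID"))
    with_dx <- if (is.null(dx)) character(0) else unique(dx$ENCOUNTERID)
    mrow("ENCOUNTER", "ENCOUNTERID",
         numerator = sum(!enc$ENCOUNTERID %in% with_dx), denominator = nrow(enc))
  })

define_rule("mapping_rx",
  expand = function(check, schema) mexpand("PRESCRIBING", "RXNORM_CUI"),
  evaluate = function(check, refresh, history, schema, years) {
    preferred <- unlist(check$params$preferred_term_types %||%
                          c("SCD", "SBD", "GPCK", "BPCK"))
    rx <- tab_or_null(refresh, "PRESCRIBING")
    if (is.null(rx)) return(mrow("PRESCRIBING", "RXNORM_CUI"))
    rxnorm <- load_code_list("codes_rxnorm.csv")
    good <- rxnorm$RXNORM_CUI[rxnorm$TTY %in% preferred]
    mrow("PRESCRIBING", "RXNORM_CUI",
         qualifier = paste(preferred, collapse = "/"),
         numerator = sum(!rx$RXNORM_CUI %in% good), denominator = nrow(rx))
  })

define_rule("mapping_loinc",
  expand = function(check, schema) mexpand("LAB_RESULT_CM", "LAB_LOINC"),
  evaluate = function(check, refresh, history, schema, years) {
    lab <- tab_or_null(refresh, "LAB_RESULT_CM")
    if (is.null(lab)) return(mrow("LAB_RESULT_CM", "LAB_LOINC"))
    known <- load_code_list("codes_loinc.csv")$LAB_LOINC
    quant <- !is.na(lab$RESULT_NUM)
    mrow("LAB_RESULT_CM", "LAB_LOINC", qualifier = "quantitative",
         numerator = sum(quant & !lab$LAB_LOINC %in% known),
         denominator = sum(quant))
  })

define_rule("lab_units",
  expand = function(check, schema) mexpand("LAB_RESULT_CM", "RESULT_UNIT"),
  evaluate = function(check, refresh, history, schema, years) {
    lab <- tab_or_null(refresh, "LAB_RESULT_CM")
    if (is.null(lab)) return(mrow("LAB_RESULT_CM", "RESULT_UNIT"))
    known_units <- unique(unlist(strsplit(load_code_list("codes_loinc.csv")$UNITS,
                                          "|", fixed = TRUE)))
    quant <- !is.na(lab$RESULT_NUM)
    mrow("LAB_RESULT_CM", "RESULT_UNIT", qualifier = "quantitative",
         numerator = sum(quant & !lab$RESULT_UNIT %in% known_units),
         denominator = sum(quant))
  })

define_rule("labs_quantitative",
  expand = function(check, schema) mexpand("LAB_RESULT_CM", "RESULT_NUM"),
  evaluate = function(check, refresh, history, schema, years) {
    lab <- tab_or_null(refresh, "LAB_RESULT_CM")
    if (is.null(lab)) return(mrow("LAB_RESULT_CM", "RESULT_NUM"))
    mrow("LAB_RESULT_CM", "RESULT_NUM",
         numerator = sum(is.na(lab$RESULT_NUM)), denominator = nrow(lab))
  })

define_rule("code_type_current",
  expand = function(check, schema) mexpand("DIAGNOSIS", "DX_TYPE", "recent"),
  evaluate = function(check, refresh, history, schema, years) {
    since <- as.Date(check$params$since %||% "2015-10-01")
    want <- unlist(check$params$expected %||% "10")
    dx <- tab_or_null(refresh, "DIAGNOSIS")
    if (is.null(dx)) return(mrow("DIAGNOSIS", "DX_TYPE", "recent"))
    scope <- !is.na(dx$DX_DATE) & dx$DX_DATE >= since & !is_missing_value(dx$DX_TYPE)
    mrow("DIAGNOSIS", "DX_TYPE", sprintf("dated >= %s", since),
         numerator = sum(scope & !dx$DX_TYPE %in% want), denominator = sum(scope))
  })

define_rule("table_populated",
  expand = function(check, schema) mexpand(check$params$table),
  evaluate = function(check, refresh, history, schema, years) {
    tn <- check$params$table
    tab <- tab_or_null(refresh, tn)
    if (is.null(tab)) return(mrow(tn))
    mrow(tn, value = nrow(tab))
  })

# DC3.07/3.11/3.14: most-recent-complete-month = latest month whose count
# reaches 50% of the median of the 12 preceding in-series months; latency =
# whole months between that month and the refresh date.
compute_latency <- function(counts, completeness = 0.5, baseline_months = 12L) {
  n <- length(counts)
  if (n < baseline_months + 1L) return(NA_real_)
  for (m in n:(baseline_months + 1L)) {
    baseline <- stats::median(counts[(m - baseline_months):(m - 1L)])
    if (counts[m] >= completeness * baseline && baseline > 0) {
      return(as.numeric(n - m))
    }
  }
  as.numeric(n - baseline_months)
}

define_rule("latency",
  expand = function(check, schema) mexpand(check$params$table, qualifier = "months"),
  evaluate = function(check, refresh, history, schema, years) {
    tn <- check$params$table
    if (is.null(tab_or_null(refresh, tn))) return(mrow(tn, qualifier = "months"))
    vs <- volume_series(refresh, schema, tn, years)
    lat <- compute_latency(vs$counts,
                           completeness = check$params$completeness %||% 0.5,
                           baseline_months = check$params$baseline_months %||% 12L)
    mrow(tn, qualifier = "months", value = lat)
  })

# ---- persistence ----------------------------------------------------------

latest_prior <- function(history) {
  ords <- vapply(history, `[[`, 0L, "refresh_ordinal")
  history[[which.max(ords)]]
}

define_rule("persistence_counts",
  expand = function(check, schema) {
    mexpand(names(schema$tables), qualifier = "vs-prior-refresh")
  },
  evaluate = function(check, refresh, history, schema, years) {
    mode <- check$params$mode %||% "records"
    if (is.null(history) || length(history) == 0) {
      return(rbind_all(lapply(names(schema$tables), function(tn)
        mrow(tn, qualifier = "vs-prior-refresh"))))
    }
    prev <- apply_lookback(latest_prior(history), schema, years)
    count_of <- function(r, tn) {
      tab <- r$tables[[tn]]
      if (is.null(tab)) return(NA_real_)
      if (mode == "patients") {
        if (!"PATID" %in% names(tab)) return(NA_real_)
        length(unique(tab$PATID[!is_missing_value(tab$PATID)]))
      } else nrow(tab)
    }
    rbind_all(lapply(names(schema$tables), function(tn) {
      cur <- count_of(refresh, tn); old <- count_of(prev, tn)
      if (is.na(cur) || is.na(old) || old == 0) {
        return(mrow(tn, qualifier = "vs-prior-refresh"))
      }
      mrow(tn, qualifier = "vs-prior-refresh", value = (cur - old) / old)
    }))
  })

define_rule("persistence_yearly",
  expand = function(check, schema) {
    tns <- unlist(check$params$tables %||%
                    c("ENCOUNTER", "DIAGNOSIS", "PROCEDURES",
                      "PRESCRIBING", "LAB_RESULT_CM"))
    mexpand(tns, qualifier = "closed-years")
  },
  evaluate = function(check, refresh, history, schema, years) {
    tns <- unlist(check$params$tables %||%
                    c("ENCOUNTER", "DIAGNOSIS", "PROCEDURES",
                      "PRESCRIBING", "LAB_RESULT_CM"))
    if (is.null(history) || length(history) == 0) {
      return(rbind_all(lapply(tns, function(tn) mrow(tn, qualifier = "closed-years"))))
    }
    prev_raw <- latest_prior(history)
    prev <- apply_lookback(prev_raw, schema, years)
    # a calendar year is comparable when fully closed at the prior refresh
    last_closed <- as.integer(format(prev_raw$refresh_date, "%Y")) - 1L
    yearly <- function(r, tn) {
      tab <- r$tables[[tn]]
      df <- schema$tables[[tn]]$date_field
      if (is.null(tab) || is.null(df) || is.na(df)) return(NULL)
      d <- tab[[df]]
      yr <- as.integer(format(d[!is.na(d)], "%Y"))
      table(yr[yr <= last_closed])
    }
    rows <- list()
    for (tn in tns) {
      cur <- yearly(refresh, tn); old <- yearly(prev, tn)
      if (is.null(cur) || is.null(old) || length(old) == 0) {
        rows[[length(rows) + 1L]] <- mrow(tn, qualifier = "closed-years")
        next
      }
      for (y in names(old)) {
        o <- as.numeric(old[[y]])
        cu <- if (y %in% names(cur)) as.numeric(cur[[y]]) else 0
        rows[[length(rows) + 1L]] <- mrow(tn, qualifier = y, value = (cu - o) / o)
      }
    }
    rbind_all(rows)
  })
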