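# curation_stats: the descriptive-statistics layer of the curation query --
# lookback windowing, frequencies, crosstabs, missing/non-missing/distinct
# counts, and monthly volume series consumed by checks and reports.

#' Apply the lookback window to a refresh
#'
#' The curation query characterizes patient-level data from the trailing
#' `years` (default 10) before the refresh date. Fact-table records older
#' than the window start are dropped; records with missing dates are
#' retained (and counted); records dated after the refresh date are
#' retained so the future-date check can see them. DEMOGRAPHIC is never
#' windowed directly: it is restricted to patients with at least one
#' retained fact record; DEATH likewise follows its patients.
#'
#' @param refresh a `datamart_refresh`.
#' @param schema a `cdm_schema` (supplies each table's date field).
#' @param years lookback length in years.
#' @return the windowed `datamart_refresh`; attribute `"lookback"` holds a
#'   per-table accounting data frame (`in_window`, `out_of_window`,
#'   `missing_date`) whose three columns sum to the original record count.
#' @export
apply_lookback <- function(refresh, schema = load_schema(), years = 10) {
  start <- years_before(refresh$refresh_date, years)
  acct <- list()
  out <- refresh
  fact_tables <- names(schema$tables)[!names(schema$tables) %in% c("DEMOGRAPHIC", "DEATH")]
  for (tn in names(out$tables)) {
    tb <- out$tables[[tn]]
    df <- schema$tables[[tn]]$date_field
    if (is.null(df) || is.na(df) || !df %in% names(tb)) {
      acct[[length(acct) + 1L]] <- data.frame(table = tn, in_window = nrow(tb),
                                              out_of_window = 0L, missing_date = 0L)
      next
    }
    d <- tb[[df]]
    missing <- is.na(d)
    old <- !missing & d < start
    acct[[length(acct) + 1L]] <- data.frame(
      table = tn, in_window = sum(!missing & !old),
      out_of_window = sum(old), missing_date = sum(missing))
    out$tables[[tn]] <- tb[!old, , drop = FALSE]
    rownames(out$tables[[tn]]) <- NULL
  }
  retained <- unique(unlist(lapply(fact_tables, function(tn) {
    tb <- out$tables[[tn]]
    if (!is.null(tb) && "PATID" %in% names(tb)) tb$PATID else character(0)
  })))
  for (tn in intersect(c("DEMOGRAPHIC", "DEATH"), names(out$tables))) {
    tb <- out$tables[[tn]]
    if ("PATID" %in% names(tb)) {
      out$tables[[tn]] <- tb[tb$PATID %in% retained, , drop = FALSE]
      rownames(out$tables[[tn]]) <- NULL
    }
  }
  attr(out, "lookback") <- rbind_all(acct)
  attr(out, "lookback_years") <- years
  out
}

format_stat_value <- function(x) {
  if (inherits(x, "Date")) ifelse(is.na(x), "", format(x, "%Y-%m-%d"))
  else if (is.numeric(x)) ifelse(is.na(x), "", as.character(x))
  else ifelse(is.na(x), "", as.character(x))
}

#' Frequency table of one field
#'
#' One row per distinct raw value (the empty-string / "NI" missing
#' sentinels appear as their own rows), with counts and percentages of the
#' table total.
#'
#' @param refresh a `datamart_refresh`.
#' @param table,field table and field name.
#' @return a `frequency_table`: list with `table`, `field`, `rows`
#'   (data frame `value`, `count`, `percent`) and `total`.
#' @export
field_frequencies <- function(refresh, table, field) {
  tb <- refresh$tables[[table]]
  if (is.null(tb)) stopf("unknown table %s", table)
  if (!field %in% names(tb)) stopf("unknown field %s.%s", table, field)
  x <- format_stat_value(tb[[field]])
  total <- length(x)
  if (total == 0) {
    rows <- data.frame(value = character(0), count = integer(0), percent = numeric(0))
  } else {
    counts <- table(x)
    rows <- data.frame(value = names(counts), count = as.integer(counts),
                       percent = 100 * as.integer(counts) / total,
                       stringsAsFactors = FALSE)
    rows <- rows[order(-rows$count, rows$value), , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(list(table = table, field = field, rows = rows, total = total),
            class = "frequency_table")
}

#' Crosstab of a field by calendar year
#'
#' Columns are the calendar years present in the table's date field (plus a
#' `"(no date)"` column when dates are missing), so the row marginals equal
#' the [field_frequencies()] totals per value.
#'
#' @param refresh a `datamart_refresh`.
#' @param schema a `cdm_schema` (supplies the table's date field).
#' @param table,field table and field name.
#' @return a `crosstab`: list with `table`, `field`, `cells` (data frame
#'   `value` x year columns) and `years`.
#' @export
crosstab_by_year <- function(refresh, schema, table, field) {
  tb <- refresh$tables[[table]]
  if (is.null(tb)) stopf("unknown table %s", table)
  df <- schema$tables[[table]]$date_field
  if (is.null(df) || is.na(df)) stopf("table %s has no date field", table)
  x <- format_stat_value(tb[[field]])
  yr <- ifelse(is.na(tb[[df]]), "(no date)", format(tb[[df]], "%Y"))
  if (length(x) == 0) {
    return(structure(list(table = table, field = field,
                          cells = data.frame(value = character(0)),
                          years = character(0)), class = "crosstab"))
  }
  tab <- table(value = x, year = yr)
  cells <- as.data.frame.matrix(tab)
  cells <- cbind(data.frame(value = rownames(cells), stringsAsFactors = FALSE),
                 cells)
  rownames(cells) <- NULL
  structure(list(table = table, field = field, cells = cells,
                 years = colnames(tab)), class = "crosstab")
}

#' Missing / non-missing / distinct counts per field
#'
#' @param refresh a `datamart_refresh`.
#' @param schema a `cdm_schema`.
#' @return a data frame with one row per (table, field): `missing`,
#'   `non_missing`, `distinct`.
#' @export
field_summaries <- function(refresh, schema = load_schema()) {
  rows <- list()
  for (tn in names(refresh$tables)) {
    tb <- refresh$tables[[tn]]
    for (fname in intersect(schema_field_names(schema, tn), names(tb))) {
      x <- tb[[fname]]
      miss <- is_missing_value(x)
      rows[[length(rows) + 1L]] <- data.frame(
        table = tn, field = fname, missing = sum(miss),
        non_missing = sum(!miss),
        distinct = length(unique(x[!miss])), stringsAsFactors = FALSE)
    }
  }
  rbind_all(rows) %||% data.frame(table = character(0), field = character(0),
                                  missing = integer(0), non_missing = integer(0),
                                  distinct = integer(0))
}

#' Monthly record-volume series for a table
#'
#' Contiguous monthly counts from the first month with data (never earlier
#' than the lookback window start) through the refresh month. The bucket
#' sum equals the number of in-window records with non-missing dates.
#'
#' @param refresh a `datamart_refresh` (typically already windowed by
#'   [apply_lookback()]).
#' @param schema a `cdm_schema`.
#' @param table table name (must have a date field).
#' @param years lookback bound used for the earliest possible month.
#' @return a `volume_series`: list with `table`, `months` (labels
#'   `"YYYY-MM"`) and `counts`.
#' @export
volume_series <- function(refresh, schema, table, years = 10) {
  df <- schema$tables[[table]]$date_field
  if (is.null(df) || is.na(df)) stopf("table %s has no date field", table)
  tb <- refresh$tables[[table]]
  ref_mi <- month_index(refresh$refresh_date)
  start_bound <- month_index(years_before(refresh$refresh_date, years))
  d <- if (is.null(tb)) as.Date(character(0)) else tb[[df]]
  d <- d[!is.na(d)]
  d <- d[month_index(d) <= ref_mi & month_index(d) >= start_bound]
  first <- if (length(d) == 0) ref_mi else max(start_bound, min(month_index(d)))
  months <- first:ref_mi
  counts <- integer(length(months))
  if (length(d) > 0) {
    tb_counts <- table(factor(month_index(d), levels = months))
    counts <- as.integer(tb_counts)
  }
  structure(list(table = table, months = month_index_to_label(months),
                 counts = counts), class = "volume_series")
}

#' Export the descriptive-statistics tables as tidy CSV files
#'
#' Writes `field_summaries.csv`, one frequency CSV per coded field, and one
#' volume-series CSV per dated table -- the machine-readable twin of the
#' EDC report's descriptive sections.
#'
#' @param refresh a `datamart_refresh`.
#' @param schema a `cdm_schema`.
#' @param directory output directory.
#' @return character vector of files written.
#' @export
write_curation_stats <- function(refresh, schema, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fs <- field_summaries(refresh, schema)
  p <- file.path(directory, "field_summaries.csv")
  utils::write.csv(fs, p, row.names = FALSE)
  files <- c(files, p)
  coded <- schema_fields_of_kind(schema, "coded")
  freq_rows <- list()
  for (i in seq_len(nrow(coded))) {
    if (is.null(refresh$tables[[coded$table[i]]])) next
    ft <- field_frequencies(refresh, coded$table[i], coded$field[i])
    if (nrow(ft$rows) > 0) {
      freq_rows[[length(freq_rows) + 1L]] <-
        cbind(data.frame(table = ft$table, field = ft$field), ft$rows)
    }
  }
  fr <- rbind_all(freq_rows)
  if (!is.null(fr)) {
    p <- file.path(directory, "field_frequencies.csv")
    utils::write.csv(fr, p, row.names = FALSE)
    files <- c(files, p)
  }
  vol_rows <- list()
  for (tn in names(schema$tables)) {
    if (is.na(schema$tables[[tn]]$date_field %||% NA)) next
    vs <- volume_series(refresh, schema, tn)
    vol_rows[[length(vol_rows) + 1L]] <-
      data.frame(table = tn, month = vs$months, count = vs$counts)
  }
  vr <- rbind_all(vol_rows)
  if (!is.null(vr)) {
    p <- file.path(directory, "volume_series.csv")
    utils::write.csv(vr, p, row.names = FALSE)
    files <- c(files, p)
  }
  files
}
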