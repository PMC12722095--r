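# DataMart refresh containers and the on-disk contract: one directory per
# refresh, one CSV per table (header row, UTF-8, comma-delimited), plus a
# refresh.json sidecar with datamart_id / refresh_date / refresh_ordinal.
#
# Value conventions inside a loaded refresh: character columns use "" (or
# the "NI" sentinel) for missing, never NA; date and numeric columns use NA.
# Hidden bookkeeping columns (names starting with ".") -- e.g. the synthetic
# generator's facility tag -- are never written to disk and are invisible to
# the check engine, which only reads schema-declared fields.

#' Construct a DataMart refresh object
#'
#' @param datamart_id identifier of the DataMart.
#' @param refresh_date `Date`; the date of this refresh.
#' @param refresh_ordinal integer position of this refresh in its history.
#' @param tables named list of data frames, one per CDM table.
#' @param audit optional defect audit log (synthetic refreshes only).
#' @param parse_errors optional data frame of unparseable raw values
#'   recorded at load time.
#' @return an object of class `datamart_refresh`.
#' @export
new_refresh <- function(datamart_id, refresh_date, refresh_ordinal, tables,
                        audit = NULL, parse_errors = NULL) {
  stopifnot(inherits(refresh_date, "Date"), is.list(tables))
  structure(list(datamart_id = as.character(datamart_id),
                 refresh_date = refresh_date,
                 refresh_ordinal = as.integer(refresh_ordinal),
                 tables = tables, audit = audit, parse_errors = parse_errors),
            class = "datamart_refresh")
}

#' @export
print.datamart_refresh <- function(x, ...) {
  cat("<datamart_refresh>", x$datamart_id, "ordinal", x$refresh_ordinal,
      "on", format(x$refresh_date), "\n")
  for (tn in names(x$tables)) cat(sprintf("  %-15s %d records\n", tn, nrow(x$tables[[tn]])))
  invisible(x)
}

visible_columns <- function(tab) tab[, !startsWith(names(tab), "."), drop = FALSE]

format_csv_column <- function(x) {
  if (inherits(x, "Date")) {
    out <- ifelse(is.na(x), "", format(x, "%Y-%m-%d"))
  } else if (is.numeric(x)) {
    out <- ifelse(is.na(x), "", vapply(x, function(v) {
      if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
    }, ""))
  } else {
    out <- ifelse(is.na(x), "", as.character(x))
  }
  out
}

#' Write a refresh to a directory
#'
#' Writes one CSV per table plus the `refresh.json` sidecar. Hidden
#' bookkeeping columns are dropped. The synthetic defect audit log, when
#' present, is written only if `include_audit = TRUE` (as
#' `audit_log.csv`, which the check engine never reads).
#'
#' @param refresh a `datamart_refresh`.
#' @param directory output directory (created if absent).
#' @param include_audit also write the synthetic audit log.
#' @return character vector manifest of the files written.
#' @export
write_refresh <- function(refresh, directory, include_audit = FALSE) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  for (tname in names(refresh$tables)) {
    tab <- visible_columns(refresh$tables[[tname]])
    out <- as.data.frame(lapply(tab, format_csv_column),
                         optional = TRUE, stringsAsFactors = FALSE)
    names(out) <- names(tab)
    path <- file.path(directory, paste0(tname, ".csv"))
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    manifest <- c(manifest, path)
  }
  sidecar <- file.path(directory, "refresh.json")
  jsonlite::write_json(list(datamart_id = refresh$datamart_id,
                            refresh_date = format(refresh$refresh_date, "%Y-%m-%d"),
                            refresh_ordinal = refresh$refresh_ordinal),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  manifest <- c(manifest, sidecar)
  if (include_audit && !is.null(refresh$audit)) {
    apath <- file.path(directory, "audit_log.csv")
    utils::write.csv(refresh$audit, apath, row.names = FALSE, quote = TRUE, na = "")
    manifest <- c(manifest, apath)
  }
  manifest
}

coerce_table <- function(raw, tname, schema) {
  spec <- schema$tables[[tname]]
  parse_errors <- list()
  out <- raw
  for (f in spec$fields) {
    if (!f$name %in% names(out)) next
    x <- out[[f$name]]
    if (f$kind %in% c("date", "datetime")) {
      parsed <- parse_iso_date(x)
      bad <- !is_missing_value(x) & is.na(parsed)
      if (any(bad)) {
        parse_errors[[length(parse_errors) + 1L]] <-
          data.frame(table = tname, field = f$name,
                     row = which(bad), value = x[bad], stringsAsFactors = FALSE)
      }
      out[[f$name]] <- parsed
    } else if (f$kind == "numeric") {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- !is_missing_value(x) & is.na(parsed)
      if (any(bad)) {
        parse_errors[[length(parse_errors) + 1L]] <-
          data.frame(table = tname, field = f$name,
                     row = which(bad), value = x[bad], stringsAsFactors = FALSE)
      }
      out[[f$name]] <- parsed
    }
  }
  list(table = out, parse_errors = rbind_all(parse_errors))
}

#' Read a refresh from a directory
#'
#' Reads every CSV whose basename matches a schema table, coerces columns to
#' their declared kinds, and records any raw value that fails to parse in
#' `$parse_errors` (these become unparseable-value findings in
#' [validate_structure()] and feed the datatype conformance check).
#'
#' @param directory a refresh directory written by [write_refresh()] (or an
#'   equivalent external layout).
#' @param schema a `cdm_schema`.
#' @return a `datamart_refresh`.
#' @export
read_refresh <- function(directory, schema) {
  sidecar <- file.path(directory, "refresh.json")
  if (!file.exists(sidecar)) stopf("no refresh.json sidecar in %s", directory)
  meta <- jsonlite::read_json(sidecar)
  tables <- list()
  errors <- list()
  for (tname in names(schema$tables)) {
    path <- file.path(directory, paste0(tname, ".csv"))
    if (!file.exists(path)) next
    raw <- utils::read.csv(path, colClasses = "character",
                           na.strings = character(0), check.names = FALSE)
    co <- coerce_table(raw, tname, schema)
    tables[[tname]] <- co$table
    if (!is.null(co$parse_errors)) errors[[length(errors) + 1L]] <- co$parse_errors
  }
  new_refresh(meta$datamart_id, as.Date(meta$refresh_date),
              meta$refresh_ordinal, tables, parse_errors = rbind_all(errors))
}

#' Construct a refresh history for one DataMart
#'
#' @param refreshes list of `datamart_refresh` objects for one DataMart,
#'   with strictly increasing refresh ordinals and dates.
#' @return an object of class `refresh_history`.
#' @export
new_refresh_history <- function(refreshes) {
  stopifnot(length(refreshes) >= 1)
  ids <- unique(vapply(refreshes, `[[`, "", "datamart_id"))
  if (length(ids) != 1) stopf("refresh history mixes DataMarts: %s", paste(ids, collapse = ", "))
  ords <- vapply(refreshes, `[[`, 0L, "refresh_ordinal")
  dates <- as.Date(vapply(refreshes, function(r) format(r$refresh_date), ""))
  if (any(diff(ords) <= 0) || any(diff(dates) <= 0)) {
    stopf("refresh ordinals and dates must be strictly increasing")
  }
  structure(list(datamart_id = ids, refreshes = refreshes),
            class = "refresh_history")
}

#' @export
print.refresh_history <- function(x, ...) {
  cat("<refresh_history>", x$datamart_id, "with", length(x$refreshes), "refreshes\n")
  invisible(x)
}

#' Read a refresh history from a directory of refresh directories
#'
#' @param directory directory whose subdirectories are individual refreshes.
#' @param schema a `cdm_schema`.
#' @return a `refresh_history`, ordered by refresh ordinal.
#' @export
read_refresh_history <- function(directory, schema) {
  subdirs <- list.dirs(directory, recursive = FALSE)
  subdirs <- subdirs[file.exists(file.path(subdirs, "refresh.json"))]
  if (length(subdirs) == 0) stopf("no refresh directories under %s", directory)
  refreshes <- lapply(subdirs, read_refresh, schema = schema)
  ords <- vapply(refreshes, `[[`, 0L, "refresh_ordinal")
  new_refresh_history(refreshes[order(ords)])
}

# Prior refreshes (ordinal < that of `refresh`) from a history, or NULL.
history_before <- function(history, refresh) {
  if (is.null(history)) return(NULL)
  prior <- Filter(function(r) r$refresh_ordinal < refresh$refresh_ordinal,
                  history$refreshes)
  if (length(prior) == 0) NULL else prior
}
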