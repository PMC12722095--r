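# reporting: the per-refresh EDC-style report, network-level summaries
# across DataMarts and cycles, and the refresh-by-refresh exception grid.

#' Build an EDC-style report for one curated refresh
#'
#' The empirical data curation (EDC) report pairs the check summary table
#' (every catalog check with its measure counts and pass/fail status) with
#' descriptive sections: per-field missing/non-missing/distinct counts,
#' frequency tables of coded fields, and monthly volume series.
#'
#' @param outcome a `curation_outcome` from [run_curation()].
#' @param refresh the (unwindowed) `datamart_refresh` the outcome was
#'   computed from; used for the descriptive sections.
#' @param schema a `cdm_schema`.
#' @param years lookback window length for the descriptive sections.
#' @return an `edc_report`.
#' @export
build_edc_report <- function(outcome, refresh = NULL, schema = load_schema(),
                             years = 10) {
  summary_tab <- outcome$check_results
  summary_tab$status <- ifelse(summary_tab$exception, "FAIL",
                               ifelse(summary_tab$n_measures ==
                                        summary_tab$n_not_applicable,
                                      "NOT APPLICABLE", "PASS"))
  descriptive <- NULL
  if (!is.null(refresh)) {
    windowed <- apply_lookback(refresh, schema, years)
    coded <- schema_fields_of_kind(schema, "coded")
    freqs <- list()
    for (i in seq_len(nrow(coded))) {
      if (is.null(windowed$tables[[coded$table[i]]])) next
      freqs[[paste(coded$table[i], coded$field[i], sep = ".")]] <-
        field_frequencies(windowed, coded$table[i], coded$field[i])
    }
    descriptive <- list(field_summaries = field_summaries(windowed, schema),
                        frequencies = freqs)
  }
  structure(list(datamart_id = outcome$datamart_id,
                 refresh_ordinal = outcome$refresh_ordinal,
                 refresh_date = outcome$refresh_date,
                 cycle = outcome$cycle,
                 summary = summary_tab,
                 measures = outcome$measures,
                 descriptive = descriptive,
                 required_exceptions = outcome$required_exceptions,
                 investigative_exceptions = outcome$investigative_exceptions,
                 approved = outcome$approved),
            class = "edc_report")
}

#' @export
print.edc_report <- function(x, ...) {
  cat("<edc_report>", x$datamart_id, "refresh", x$refresh_ordinal,
      if (x$approved) "APPROVED" else "NOT APPROVED", "\n")
  invisible(x)
}

summary_to_markdown <- function(s) {
  hdr <- "| check | category | classification | measures | exceptions | status |"
  sep <- "|---|---|---|---|---|---|"
  rows <- sprintf("| %s | %s | %s | %d | %d | %s |", s$check_id, s$category,
                  s$classification, s$n_measures, s$n_exceptions, s$status)
  paste(c(hdr, sep, rows), collapse = "\n")
}

report_to_list <- function(report) {
  list(datamart_id = report$datamart_id,
       refresh_ordinal = report$refresh_ordinal,
       refresh_date = format(report$refresh_date, "%Y-%m-%d"),
       cycle = report$cycle,
       required_exceptions = report$required_exceptions,
       investigative_exceptions = report$investigative_exceptions,
       approved = report$approved,
       summary = report$summary,
       measures = report$measures)
}

#' Render an EDC report
#'
#' JSON round-trips losslessly through [parse_report_json()]; the markdown
#' and HTML renderings carry the header, the approval banner and the check
#' summary table.
#'
#' @param report an `edc_report`.
#' @param format one of `"json"`, `"markdown"`, `"html"`.
#' @param path optional output file.
#' @return the rendered document as a character scalar (invisibly when
#'   written to `path`).
#' @export
render_report <- function(report, format = c("json", "markdown", "html"),
                          path = NULL) {
  if (!format[1] %in% c("json", "markdown", "html")) {
    stopf("usage error: unknown report format '%s'", format[1])
  }
  format <- format[1]
  doc <- switch(format,
    json = jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                            dataframe = "rows", digits = NA, pretty = TRUE,
                            na = "null"),
    markdown = paste0(
      sprintf("# Empirical data curation report: %s\n\n", report$datamart_id),
      sprintf("- refresh: %d (%s), cycle %s\n", report$refresh_ordinal,
              format.Date(report$refresh_date), report$cycle),
      sprintf("- required exceptions: %d; investigative exceptions: %d\n",
              report$required_exceptions, report$investigative_exceptions),
      sprintf("- **%s**\n\n", if (report$approved) "APPROVED" else "NOT APPROVED"),
      summary_to_markdown(report$summary), "\n"),
    html = {
      s <- report$summary
      rows <- sprintf(paste0("<tr><td>%s</td><td>%s</td><td>%s</td>",
                             "<td>%d</td><td>%d</td><td>%s</td></tr>"),
                      s$check_id, s$category, s$classification, s$n_measures,
                      s$n_exceptions, s$status)
      paste0("<html><body><h1>Empirical data curation report: ",
             report$datamart_id, "</h1><p>refresh ", report$refresh_ordinal,
             " (", format.Date(report$refresh_date), "), cycle ", report$cycle,
             "</p><p>required exceptions: ", report$required_exceptions,
             "; investigative exceptions: ", report$investigative_exceptions,
             "</p><p><b>", if (report$approved) "APPROVED" else "NOT APPROVED",
             "</b></p><table border='1'><tr><th>check</th><th>category</th>",
             "<th>classification</th><th>measures</th><th>exceptions</th>",
             "<th>status</th></tr>", paste(rows, collapse = ""),
             "</table></body></html>")
    })
  doc <- as.character(doc)
  if (!is.null(path)) { writeLines(doc, path); return(invisible(doc)) }
  doc
}

#' Parse a JSON-rendered EDC report back into an `edc_report`
#'
#' @param json JSON text (or a file path) produced by
#'   `render_report(format = "json")`.
#' @return an `edc_report` (descriptive sections are not serialized).
#' @export
parse_report_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(datamart_id = x$datamart_id,
                 refresh_ordinal = x$refresh_ordinal,
                 refresh_date = as.Date(x$refresh_date),
                 cycle = x$cycle,
                 summary = as.data.frame(x$summary),
                 measures = as.data.frame(x$measures),
                 descriptive = NULL,
                 required_exceptions = x$required_exceptions,
                 investigative_exceptions = x$investigative_exceptions,
                 approved = x$approved),
            class = "edc_report")
}

#' Summarize a network of curated DataMarts, per cycle
#'
#' For each cycle: per-check exception prevalence (how many DataMarts with
#' an exception, as a percentage of the DataMarts where the check was
#' applicable), the distribution (median/min/max) of investigative
#' exception counts per DataMart, and -- when a prior cycle is available --
#' the percentage of DataMarts with fewer investigative exceptions than in
#' the prior cycle.
#'
#' @param outcomes_by_cycle named list: cycle label -> list of
#'   `curation_outcome` objects (one per DataMart).
#' @return named list of `network_summary` objects, one per cycle.
#' @export
summarize_network <- function(outcomes_by_cycle) {
  cycles <- names(outcomes_by_cycle)
  out <- list()
  prev_counts <- NULL
  for (cy in cycles) {
    outcomes <- outcomes_by_cycle[[cy]]
    stopifnot(length(outcomes) >= 1)
    cr <- rbind_all(lapply(outcomes, function(o) {
      cbind(o$check_results, datamart_id = o$datamart_id)
    }))
    prev_rows <- list()
    for (cid in unique(cr$check_id)) {
      sub <- cr[cr$check_id == cid, , drop = FALSE]
      applicable <- sub$n_measures > sub$n_not_applicable
      n_app <- sum(applicable)
      n_exc <- sum(sub$exception[applicable])
      prev_rows[[length(prev_rows) + 1L]] <- data.frame(
        check_id = cid, n_applicable = n_app, n_exceptions = n_exc,
        percent = if (n_app > 0) 100 * n_exc / n_app else NA_real_,
        stringsAsFactors = FALSE)
    }
    inv <- vapply(outcomes, `[[`, 0, "investigative_exceptions")
    names(inv) <- vapply(outcomes, `[[`, "", "datamart_id")
    improvement <- NA_real_
    if (!is.null(prev_counts)) {
      common <- intersect(names(inv), names(prev_counts))
      if (length(common) > 0) {
        improvement <- 100 * mean(inv[common] < prev_counts[common])
      }
    }
    out[[cy]] <- structure(
      list(cycle = cy, prevalence = rbind_all(prev_rows),
           exceptions = list(median = stats::median(inv), min = min(inv),
                             max = max(inv)),
           improvement_pct = improvement,
           n_datamarts = length(outcomes)),
      class = "network_summary")
    prev_counts <- inv
  }
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary>", x$cycle, "-", x$n_datamarts, "DataMarts;",
      "investigative exceptions median", x$exceptions$median,
      sprintf("(min %d, max %d)\n", x$exceptions$min, x$exceptions$max))
  invisible(x)
}

#' Refresh-by-refresh exception grid for one check
#'
#' Rows are DataMarts, columns refresh ordinals; each cell is
#' `"exception"`, `"pass"`, or `"not_submitted"` (the refresh is absent
#' from that DataMart's history).
#'
#' @param histories list of `refresh_history` objects.
#' @param check_id the check to grid.
#' @param catalog a `check_catalog` containing the check.
#' @param schema a `cdm_schema`.
#' @param years lookback window length.
#' @return a `refresh_grid`: list with `check_id`, `datamarts`, `ordinals`
#'   and `cells` (character matrix).
#' @export
build_refresh_grid <- function(histories, check_id, catalog = load_catalog(),
                               schema = load_schema(), years = 10) {
  check <- catalog$checks[[check_id]]
  if (is.null(check)) stopf("unknown check_id %s", check_id)
  present <- unlist(lapply(histories, function(h) {
    vapply(h$refreshes, `[[`, 0L, "refresh_ordinal")
  }))
  # span the full ordinal range so skipped refreshes show as gray columns
  ords <- seq(min(present), max(present))
  marts <- vapply(histories, `[[`, "", "datamart_id")
  cells <- matrix("not_submitted", nrow = length(marts), ncol = length(ords),
                  dimnames = list(marts, as.character(ords)))
  for (h in histories) {
    for (r in h$refreshes) {
      prior <- history_before(h, r)
      windowed <- apply_lookback(r, schema, years)
      res <- evaluate_check(check, windowed, prior, schema, years)
      cells[h$datamart_id, as.character(r$refresh_ordinal)] <-
        if (any(res$status == "exception")) "exception" else "pass"
    }
  }
  structure(list(check_id = check_id, datamarts = marts,
                 ordinals = ords, cells = cells), class = "refresh_grid")
}

#' Render a refresh grid as CSV or a colored HTML table
#'
#' @param grid a `refresh_grid`.
#' @param format `"csv"` or `"html"`.
#' @param path optional output file.
#' @return the rendered document (invisibly when written to `path`).
#' @export
render_refresh_grid <- function(grid, format = c("csv", "html"), path = NULL) {
  format <- match.arg(format)
  doc <- if (format == "csv") {
    df <- cbind(data.frame(datamart_id = grid$datamarts), as.data.frame(grid$cells))
    tc <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, tc, row.names = FALSE)
    close(tc)
    paste(out, collapse = "\n")
  } else {
    colr <- c(exception = "#e8833a", pass = "#62a563", not_submitted = "#b3b3b3")
    rows <- vapply(seq_along(grid$datamarts), function(i) {
      tds <- sprintf("<td style='background:%s'>%s</td>",
                     colr[grid$cells[i, ]], grid$cells[i, ])
      paste0("<tr><td>", grid$datamarts[i], "</td>", paste(tds, collapse = ""), "</tr>")
    }, "")
    paste0("<html><body><h2>", grid$check_id, " by refresh</h2>",
           "<table border='1'><tr><th>DataMart</th>",
           paste(sprintf("<th>%s</th>", grid$ordinals), collapse = ""),
           "</tr>", paste(rows, collapse = ""), "</table></body></html>")
  }
  if (!is.null(path)) { writeLines(doc, path); return(invisible(doc)) }
  doc
}
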