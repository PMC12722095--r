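# check_engine: data checks and measures, threshold application, catalog
# loading, refresh-level curation and approval gating.
#
# A check is a broad rule (e.g. "coded values lie in their value set"); a
# measure is its instantiation on one table/field/stratum. Measures are
# evaluated to numerator/denominator (proportion metrics) or to a scalar
# metric value (ratio, months, relative change, absolute count), and the
# check's threshold assigns pass/exception/not_applicable per measure. A
# check has an exception iff any of its measures does; not_applicable
# measures never contribute. Approval requires zero required-check
# exceptions.

CHECK_CATEGORIES <- c("conformance", "completeness", "plausibility", "persistence")
CHECK_CLASSIFICATIONS <- c("required", "investigative")
THRESHOLD_METRICS <- c("proportion", "absolute_count", "relative_change",
                       "months", "ratio")

#' Construct a threshold
#'
#' The comparator expresses the PASS condition: a proportion threshold
#' `lt 0.05` passes while the error proportion is strictly below 5% (the
#' network's default), so a proportion exactly at the threshold value is an
#' exception. Metric `ratio` uses a closed band `[value, value_high]`.
#'
#' @param metric one of proportion, absolute_count, relative_change,
#'   months, ratio.
#' @param comparator one of lt, le, gt, ge (or "between" for ratio bands).
#' @param value threshold value (band low for ratio).
#' @param value_high band high (ratio only).
#' @param note free-text direction note.
#' @return a `dq_threshold`.
#' @export
threshold <- function(metric = "proportion", comparator = "lt", value = 0.05,
                      value_high = NULL, note = "") {
  if (!metric %in% THRESHOLD_METRICS) stopf("unknown threshold metric '%s'", metric)
  if (!comparator %in% c("lt", "le", "gt", "ge", "between")) {
    stopf("unknown comparator '%s'", comparator)
  }
  if (metric == "proportion" && (value < 0 || value > 1)) {
    stopf("proportion thresholds must lie in [0, 1]")
  }
  if (metric == "ratio" && is.null(value_high)) {
    stopf("ratio thresholds need value_high (closed band)")
  }
  structure(list(metric = metric, comparator = comparator, value = value,
                 value_high = value_high, note = note), class = "dq_threshold")
}

compare_pass <- function(comparator, x, value, value_high = NULL) {
  switch(comparator,
         lt = x < value, le = x <= value, gt = x > value, ge = x >= value,
         between = x >= value & x <= value_high)
}

# status of one measure row under a threshold
measure_status <- function(th, numerator, denominator, value) {
  if (th$metric == "proportion") {
    if (is.na(denominator) || denominator == 0) return("not_applicable")
    p <- numerator / denominator
    if (compare_pass(th$comparator, p, th$value)) "pass" else "exception"
  } else {
    if (is.na(value)) return("not_applicable")
    if (compare_pass(th$comparator, value, th$value, th$value_high)) "pass" else "exception"
  }
}

#' Load a data-check catalog
#'
#' Catalogs are versioned by curation-cycle label. The packaged `"cycle16"`
#' catalog holds 46 checks across the four categories; `"cycle7"` holds the
#' 36 of them already active in that earlier cycle. Each check carries a
#' provenance flag (`named` for checks named in the network's reports,
#' `reconstructed` for catalog slots filled by this package).
#'
#' @param source `"cycle16"`, `"cycle7"`, a path to a catalog YAML, or a
#'   parsed list.
#' @param schema a `cdm_schema` used to validate that check rules can be
#'   instantiated.
#' @return a `check_catalog`: list with `cycle` and `checks` (named list of
#'   `data_check` objects).
#' @export
load_catalog <- function(source = "cycle16", schema = load_schema()) {
  if (is.character(source) && source %in% c("cycle16", "cycle7")) {
    source <- cdm_resource(paste0("catalog_", source, ".yaml"))
  }
  doc <- if (is.character(source)) yaml::read_yaml(source) else source
  checks <- list()
  for (cdoc in doc$checks %||% list()) {
    id <- cdoc$id
    if (is.null(id)) stopf("catalog parse error: check without id")
    if (id %in% names(checks)) stopf("catalog error: duplicate check_id %s", id)
    if (!cdoc$category %in% CHECK_CATEGORIES) {
      stopf("catalog parse error: check %s has unknown category '%s'", id, cdoc$category)
    }
    if (!cdoc$classification %in% CHECK_CLASSIFICATIONS) {
      stopf("catalog parse error: check %s has unknown classification '%s'",
            id, cdoc$classification)
    }
    if (!rule_exists(cdoc$rule %||% "")) {
      stopf("catalog parse error: check %s names unknown rule '%s'", id, cdoc$rule)
    }
    tdoc <- cdoc$threshold %||% list()
    th <- threshold(metric = tdoc$metric %||% "proportion",
                    comparator = tdoc$comparator %||% "lt",
                    value = tdoc$value %||% 0.05,
                    value_high = tdoc$value_high,
                    note = tdoc$note %||% "")
    checks[[id]] <- structure(
      list(check_id = id, category = cdoc$category,
           classification = cdoc$classification,
           description = cdoc$description %||% "",
           rule = cdoc$rule, params = cdoc$params %||% list(),
           threshold = th,
           needs_history = cdoc$category == "persistence",
           provenance = cdoc$provenance %||% "reconstructed",
           added_after_cycle7 = isTRUE(cdoc$added_after_cycle7)),
      class = "data_check")
  }
  structure(list(cycle = doc$cycle %||% "unlabeled", checks = checks),
            class = "check_catalog")
}

#' @export
print.check_catalog <- function(x, ...) {
  cats <- table(vapply(x$checks, `[[`, "", "category"))
  cat("<check_catalog>", x$cycle, "with", length(x$checks), "checks\n")
  print(cats)
  invisible(x)
}

#' Enumerate the measures of a catalog against a schema
#'
#' @param catalog a `check_catalog`.
#' @param schema a `cdm_schema`.
#' @return data frame (`check_id`, `table`, `field`, `qualifier`), one row
#'   per measure.
#' @export
catalog_measures <- function(catalog, schema = load_schema()) {
  rows <- lapply(catalog$checks, function(check) {
    m <- rule_expand(check, schema)
    if (is.null(m) || nrow(m) == 0) return(NULL)
    cbind(data.frame(check_id = check$check_id, stringsAsFactors = FALSE), m)
  })
  rbind_all(rows)
}

#' Evaluate one check against a (windowed) refresh
#'
#' @param check a `data_check`.
#' @param refresh a `datamart_refresh`, already windowed via
#'   [apply_lookback()] for faithful curation semantics.
#' @param history optional list of prior `datamart_refresh` objects
#'   (required when `check$needs_history`).
#' @param schema a `cdm_schema`.
#' @param years lookback window length passed through to history handling.
#' @param strict_history error (rather than return not_applicable measures)
#'   when a history-dependent check lacks a history.
#' @return data frame of measure results: `check_id`, `table`, `field`,
#'   `qualifier`, `numerator`, `denominator`, `proportion`, `value`,
#'   `status`.
#' @export
evaluate_check <- function(check, refresh, history = NULL,
                           schema = load_schema(), years = 10,
                           strict_history = FALSE) {
  if (check$needs_history && is.null(history) && strict_history) {
    stopf("evaluation error: check %s needs a refresh history", check$check_id)
  }
  rows <- rule_evaluate(check, refresh, history, schema, years)
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- data.frame(table = NA_character_, field = NA_character_,
                       qualifier = NA_character_, numerator = NA_real_,
                       denominator = NA_real_, value = NA_real_,
                       stringsAsFactors = FALSE)
  }
  rows$proportion <- ifelse(!is.na(rows$denominator) & rows$denominator > 0,
                            rows$numerator / rows$denominator, NA_real_)
  rows$status <- vapply(seq_len(nrow(rows)), function(i) {
    measure_status(check$threshold, rows$numerator[i], rows$denominator[i],
                   rows$value[i])
  }, "")
  cbind(data.frame(check_id = check$check_id, stringsAsFactors = FALSE),
        rows[, c("table", "field", "qualifier", "numerator", "denominator",
                 "proportion", "value", "status")])
}

#' Evaluate a single measure
#'
#' Restricts [evaluate_check()] to one (table, field, qualifier)
#' instantiation. A measure whose table is absent from the refresh has
#' status `not_applicable`.
#'
#' @param check the owning `data_check`.
#' @param measure list or one-row data frame with `table` and optionally
#'   `field`, `qualifier`.
#' @inheritParams evaluate_check
#' @return a one-row measure-result data frame.
#' @export
evaluate_measure <- function(check, measure, refresh, history = NULL,
                             schema = load_schema(), years = 10) {
  if (check$needs_history && is.null(history)) {
    stopf("evaluation error: check %s needs a refresh history", check$check_id)
  }
  res <- evaluate_check(check, refresh, history, schema, years)
  sel <- rep(TRUE, nrow(res))
  if (!is.null(measure$table)) sel <- sel & (is.na(res$table) | res$table == measure$table)
  if (!is.null(measure$field) && !is.na(measure$field %||% NA)) {
    sel <- sel & !is.na(res$field) & res$field == measure$field
  }
  if (!is.null(measure$qualifier) && !is.na(measure$qualifier %||% NA)) {
    sel <- sel & !is.na(res$qualifier) & res$qualifier == measure$qualifier
  }
  out <- res[sel, , drop = FALSE]
  if (nrow(out) == 0) {
    out <- evaluate_check(check, new_refresh(refresh$datamart_id,
                                             refresh$refresh_date,
                                             refresh$refresh_ordinal,
                                             list()), NULL, schema, years)[0, ]
    out[1, ] <- list(check$check_id, measure$table %||% NA_character_,
                     measure$field %||% NA_character_,
                     measure$qualifier %||% NA_character_,
                     NA_real_, NA_real_, NA_real_, NA_real_, "not_applicable")
  }
  rownames(out) <- NULL
  out
}

#' Run the full curation query on one refresh
#'
#' Applies the lookback window, evaluates every catalog check, aggregates
#' measure exceptions to check level, and decides approval: a refresh is
#' approved iff it has zero required-check exceptions (investigative
#' exceptions must be investigated but do not block).
#'
#' @param refresh a `datamart_refresh` (unwindowed; the lookback window is
#'   applied here).
#' @param history optional `refresh_history` (or list of refreshes) of
#'   prior refreshes for the persistence checks.
#' @param catalog a `check_catalog`.
#' @param schema a `cdm_schema`.
#' @param years lookback window length (years).
#' @return a `curation_outcome`: list with `datamart_id`,
#'   `refresh_ordinal`, `refresh_date`, `measures` (all measure results),
#'   `check_results` (one row per check), `required_exceptions`,
#'   `investigative_exceptions`, `approved`.
#' @export
run_curation <- function(refresh, history = NULL, catalog = load_catalog(),
                         schema = load_schema(), years = 10) {
  if (inherits(history, "refresh_history")) history <- history$refreshes
  prior <- if (is.null(history)) NULL else {
    Filter(function(r) r$refresh_ordinal < refresh$refresh_ordinal, history)
  }
  if (!is.null(prior) && length(prior) == 0) prior <- NULL
  windowed <- apply_lookback(refresh, schema, years)

  measures <- rbind_all(lapply(catalog$checks, function(check) {
    evaluate_check(check, windowed, prior, schema, years)
  }))

  check_results <- rbind_all(lapply(catalog$checks, function(check) {
    m <- measures[measures$check_id == check$check_id, , drop = FALSE]
    data.frame(check_id = check$check_id, category = check$category,
               classification = check$classification,
               n_measures = nrow(m),
               n_exceptions = sum(m$status == "exception"),
               n_not_applicable = sum(m$status == "not_applicable"),
               exception = any(m$status == "exception"),
               stringsAsFactors = FALSE)
  }))
  check_results <- check_results[order(check_results$check_id), , drop = FALSE]
  rownames(check_results) <- NULL

  required_exceptions <- sum(check_results$exception &
                               check_results$classification == "required")
  investigative_exceptions <- sum(check_results$exception &
                                    check_results$classification == "investigative")
  structure(list(datamart_id = refresh$datamart_id,
                 refresh_ordinal = refresh$refresh_ordinal,
                 refresh_date = refresh$refresh_date,
                 cycle = catalog$cycle,
                 measures = measures, check_results = check_results,
                 required_exceptions = required_exceptions,
                 investigative_exceptions = investigative_exceptions,
                 approved = required_exceptions == 0),
            class = "curation_outcome")
}

#' @export
print.curation_outcome <- function(x, ...) {
  cat("<curation_outcome>", x$datamart_id, "refresh", x$refresh_ordinal, "\n")
  cat(sprintf("  required exceptions: %d, investigative: %d -> %s\n",
              x$required_exceptions, x$investigative_exceptions,
              if (x$approved) "APPROVED" else "NOT APPROVED"))
  invisible(x)
}

#' Propose per-check thresholds from simulated network performance
#'
#' The network derives heuristic thresholds from observed performance
#' (e.g. the 80th percentile of DataMart error proportions). This offline
#' calibration utility proposes, for every proportion-based check, the
#' given percentile of the per-DataMart worst measure proportion. It never
#' changes a catalog at evaluation time.
#'
#' @param outcomes list of `curation_outcome` objects (one per DataMart).
#' @param percentile percentile of network performance to propose.
#' @return data frame `check_id`, `n_datamarts`, `proposed_value`.
#' @export
calibrate_thresholds <- function(outcomes, percentile = 0.8) {
  rows <- list()
  all_m <- rbind_all(lapply(outcomes, function(o) {
    cbind(o$measures, datamart_id = o$datamart_id)
  }))
  for (cid in unique(all_m$check_id)) {
    m <- all_m[all_m$check_id == cid & !is.na(all_m$proportion), , drop = FALSE]
    if (nrow(m) == 0) next
    worst <- tapply(m$proportion, m$datamart_id, max)
    rows[[length(rows) + 1L]] <- data.frame(
      check_id = cid, n_datamarts = length(worst),
      proposed_value = unname(stats::quantile(worst, percentile, type = 7)),
      stringsAsFactors = FALSE)
  }
  rbind_all(rows)
}
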