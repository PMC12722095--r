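# Shared internal helpers: missing-value convention, date/month arithmetic,
# seed scoping. The missing convention (empty string, NA, or the "NI"
# no-information sentinel) is load-bearing for every completeness rule.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Missing-value test under the CDM convention
#'
#' A value is considered missing when it is `NA`, the empty string, or the
#' "no information" sentinel `"NI"`. Numeric and Date vectors are missing
#' only when `NA`.
#'
#' @param x vector of values.
#' @return logical vector, `TRUE` where the value counts as missing.
#' @export
is_missing_value <- function(x) {
  if (is.character(x)) {
    is.na(x) | x == "" | x == "NI"
  } else {
    is.na(x)
  }
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Month index (months since year 0) and its inverse; used for volume series
# and latency arithmetic so month differences are exact integers.
month_index <- function(dates) {
  lt <- as.POSIXlt(dates)
  (lt$year + 1900L) * 12L + lt$mon
}

month_index_to_label <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

month_label <- function(dates) {
  format(dates, "%Y-%m")
}

# First day of the month `n` months after the month containing `date`.
add_months <- function(date, n) {
  idx <- month_index(date) + as.integer(n)
  as.Date(sprintf("%04d-%02d-01", idx %/% 12L, idx %% 12L + 1L))
}

# Same calendar day `years` earlier; Feb 29 falls back to Feb 28.
years_before <- function(date, years) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L - as.integer(years)
  d <- as.Date(sprintf("%04d-%02d-%02d", y, lt$mon + 1L, lt$mday))
  if (is.na(d)) d <- as.Date(sprintf("%04d-%02d-%02d", y, lt$mon + 1L, lt$mday - 1L))
  d
}

parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}", x)
  if (any(ok)) {
    parsed <- as.Date(substr(x[ok], 1L, 10L), format = "%Y-%m-%d")
    out[ok] <- parsed
  }
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Path to a packaged resource under inst/extdata.
cdm_resource <- function(...) {
  path <- system.file("extdata", ..., package = "cdmcurate")
  if (path == "") stopf("packaged resource not found: %s", file.path(...))
  path
}

empty_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame", row.names = integer(0))
}

rbind_all <- function(dfs) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, dfs)
  if (length(dfs) == 0) return(NULL)
  do.call(rbind, c(dfs, list(make.row.names = FALSE)))
}
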