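# check_engine: catalog loading, threshold semantics, measure evaluation,
# curation and approval gating, threshold calibration.

test_that("packaged catalogs load with their cycle's check counts", {
  cat16 <- test_catalog()
  expect_length(cat16$checks, 46)
  cat7 <- load_catalog("cycle7", test_schema())
  expect_length(cat7$checks, 36)
  # cycle7 is a strict subset of cycle16
  expect_true(all(names(cat7$checks) %in% names(cat16$checks)))
  # all four categories are populated, and persistence checks need history
  cats <- vapply(cat16$checks, `[[`, "", "category")
  expect_setequal(unique(cats),
                  c("conformance", "completeness", "plausibility", "persistence"))
  for (ck in cat16$checks) {
    expect_identical(ck$needs_history, ck$category == "persistence")
  }
  # empty catalog document
  expect_length(load_catalog(list(cycle = "x", checks = list()))$checks, 0)
})

test_that("catalog parse errors name the offending construct", {
  bad_cat <- list(checks = list(
    list(id = "A", category = "nope", classification = "required",
         rule = "pk_uniqueness")))
  expect_error(load_catalog(bad_cat), "unknown category")
  dup <- list(checks = list(
    list(id = "A", category = "conformance", classification = "required",
         rule = "pk_uniqueness"),
    list(id = "A", category = "conformance", classification = "required",
         rule = "pk_uniqueness")))
  expect_error(load_catalog(dup), "duplicate check_id")
  unk <- list(checks = list(
    list(id = "A", category = "conformance", classification = "required",
         rule = "no_such_rule")))
  expect_error(load_catalog(unk), "unknown rule")
})

test_that("measure expansion counts designated fields and schema shape", {
  cat16 <- test_catalog()
  m <- catalog_measures(cat16, test_schema())
  # the missingness check instantiates one measure per designated field
  k <- length(cat16$checks[["DC3.03"]]$params$fields)
  expect_identical(sum(m$check_id == "DC3.03"), k)
  # every check contributes at least one measure
  expect_setequal(unique(m$check_id), names(cat16$checks))
  expect_gt(nrow(m), length(cat16$checks))
})

test_that("threshold comparators encode the pass condition exactly", {
  th <- threshold("proportion", "lt", 0.05)
  expect_identical(cdmcurate:::measure_status(th, 4, 100, NA), "pass")
  expect_identical(cdmcurate:::measure_status(th, 5, 100, NA), "exception")
  expect_identical(cdmcurate:::measure_status(th, 6, 100, NA), "exception")
  # denominator zero is never an exception
  expect_identical(cdmcurate:::measure_status(th, 0, 0, NA), "not_applicable")
  th0 <- threshold("proportion", "le", 0)
  expect_identical(cdmcurate:::measure_status(th0, 0, 10, NA), "pass")
  expect_identical(cdmcurate:::measure_status(th0, 1, 10, NA), "exception")
  # closed ratio band
  band <- threshold("ratio", "between", 1, value_high = 1.5)
  expect_identical(cdmcurate:::measure_status(band, NA, NA, 1.0), "pass")
  expect_identical(cdmcurate:::measure_status(band, NA, NA, 1.5), "pass")
  expect_identical(cdmcurate:::measure_status(band, NA, NA, 1.51), "exception")
  # months: pass while at or under the latency bound
  lat <- threshold("months", "le", 3)
  expect_identical(cdmcurate:::measure_status(lat, NA, NA, 3), "pass")
  expect_identical(cdmcurate:::measure_status(lat, NA, NA, 4), "exception")
  expect_error(threshold("proportion", "lt", 1.5), "\\[0, 1\\]")
})

test_that("evaluate_measure targets one instantiation and guards history", {
  cat16 <- test_catalog()
  w <- apply_lookback(clean_refresh(), test_schema())
  res <- evaluate_measure(cat16$checks[["DC2.01"]],
                          list(table = "ENCOUNTER", field = "ADMIT_DATE"), w)
  expect_identical(nrow(res), 1L)
  expect_identical(res$status, "pass")
  # absent table -> not_applicable
  r_empty <- new_refresh("X", as.Date("2024-12-31"), 1L, list())
  res2 <- evaluate_measure(cat16$checks[["DC2.01"]],
                           list(table = "ENCOUNTER", field = "ADMIT_DATE"),
                           r_empty)
  expect_identical(res2$status, "not_applicable")
  # persistence without history is an evaluation error at measure level
  expect_error(
    evaluate_measure(cat16$checks[["DC4.01"]], list(table = "ENCOUNTER"), w),
    "needs a refresh history")
})

test_that("curation is idempotent and gates approval on required checks", {
  out1 <- clean_outcome()
  out2 <- run_curation(clean_refresh(), NULL, test_catalog(), test_schema())
  expect_identical(out1$measures, out2$measures)
  expect_identical(out1$check_results, out2$check_results)
  expect_true(out1$approved)
  expect_identical(out1$required_exceptions, 0L)
  expect_identical(out1$investigative_exceptions, 0L)

  # a missing required table is a required conformance exception
  broken <- clean_refresh()
  broken$tables$DEMOGRAPHIC <- NULL
  outb <- run_curation(broken, NULL, test_catalog(), test_schema())
  expect_false(outb$approved)
  expect_gt(outb$required_exceptions, 0)
  expect_true(outb$check_results$exception[outb$check_results$check_id == "DC1.01"])

  # investigative-only exceptions do not block approval
  noisy <- generate_datamart(population_config(n_patients = 200, seed = 101),
                             error_profile(missing_lab_unit_rate = 0.3))
  outn <- run_curation(noisy, NULL, test_catalog(), test_schema())
  expect_gt(outn$investigative_exceptions, 0)
  expect_identical(outn$required_exceptions, 0L)
  expect_true(outn$approved)
})

test_that("threshold calibration proposes the requested network percentile", {
  outs <- lapply(seq(0.01, 0.10, by = 0.01), function(p) {
    m <- data.frame(check_id = "DCX", table = "T", field = "F",
                    qualifier = NA, numerator = round(100 * p),
                    denominator = 100, proportion = p, value = NA,
                    status = "pass")
    structure(list(datamart_id = paste0("DM", p), measures = m),
              class = "curation_outcome")
  })
  cal <- calibrate_thresholds(outs, percentile = 0.8)
  props <- seq(0.01, 0.10, by = 0.01)
  expect_equal(cal$proposed_value, unname(quantile(props, 0.8)))
  expect_identical(cal$n_datamarts, 10L)
})
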