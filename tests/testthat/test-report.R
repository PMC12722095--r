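# reporting_cli: EDC report construction and rendering, network summaries,
# refresh grids, and the command-line front end.

test_that("EDC report totals are consistent and every check appears once", {
  outcome <- clean_outcome()
  report <- build_edc_report(outcome, clean_refresh(), test_schema())
  expect_identical(sort(report$summary$check_id), sort(names(test_catalog()$checks)))
  expect_identical(nrow(report$summary), 46L)
  expect_identical(sum(report$summary$status == "FAIL" &
                         report$summary$classification == "required"),
                   report$required_exceptions)
  expect_true(report$approved)
  # not-applicable checks are surfaced but excluded from exception totals
  na_rows <- report$summary[report$summary$status == "NOT APPLICABLE", ]
  expect_true(all(na_rows$n_exceptions == 0))
})

test_that("report rendering round-trips JSON and embeds the summary table", {
  report <- build_edc_report(clean_outcome(), clean_refresh(), test_schema())
  js <- render_report(report, "json")
  back <- parse_report_json(js)
  expect_identical(back$datamart_id, report$datamart_id)
  expect_identical(back$approved, report$approved)
  expect_equal(back$summary, report$summary, ignore_attr = TRUE)
  md <- render_report(report, "markdown")
  expect_true(all(vapply(report$summary$check_id, grepl, TRUE, x = md,
                         fixed = TRUE)))
  html <- render_report(report, "html")
  expect_true(grepl("<table", html, fixed = TRUE))
  expect_error(render_report(report, "pdf"), "usage error")
})

test_that("network summaries compute prevalence, distribution, improvement", {
  # two DataMarts, one with a single investigative exception
  clean <- clean_outcome()
  noisy <- run_curation(
    generate_datamart(population_config(n_patients = 200, seed = 103),
                      error_profile(missing_lab_unit_rate = 0.3),
                      datamart_id = "DM02"),
    NULL, test_catalog(), test_schema())
  expect_true(noisy$check_results$exception[
    noisy$check_results$check_id == "DC3.12"])
  s <- summarize_network(list(cycleA = list(clean, noisy)))$cycleA
  p312 <- s$prevalence[s$prevalence$check_id == "DC3.12", ]
  expect_equal(p312$percent, 50)
  expect_identical(p312$n_exceptions, 1L)
  # all-clean network
  s0 <- summarize_network(list(c1 = list(clean, clean)))$c1
  expect_true(all(s0$prevalence$n_exceptions == 0))
  expect_identical(s0$exceptions$median, 0)
  # median recovered against a brute-force count
  counts <- c(clean$investigative_exceptions, noisy$investigative_exceptions)
  expect_identical(s$exceptions$median, median(counts))
  # improvement: second cycle all clean -> the noisy mart improved
  s2 <- summarize_network(list(c1 = list(clean, noisy),
                               c2 = list(clean, {
                                 x <- noisy; x$investigative_exceptions <- 0L; x
                               })))
  expect_equal(s2$c2$improvement_pct, 50)
})

test_that("refresh grid reproduces exception/pass/not-submitted semantics", {
  pop <- population_config(n_patients = 120, seed = 5)
  scen <- refresh_scenario(n_refreshes = 5, events = list(
    list(ordinal = 3, kind = "feed_loss", magnitude = 0.2),
    list(ordinal = 2, kind = "no_submission")))
  hist <- generate_refresh_sequence(pop, error_profile(), scen, test_schema())
  grid <- build_refresh_grid(list(hist), "DC4.01", test_catalog(), test_schema())
  expect_identical(dim(grid$cells), c(1L, 5L))
  expect_identical(grid$cells[1, "2"], "not_submitted")
  expect_identical(grid$cells[1, "3"], "exception")
  expect_identical(unname(grid$cells[1, c("1", "4", "5")]),
                   rep("pass", 3))
  expect_error(build_refresh_grid(list(hist), "DC9.99"), "unknown check_id")
  csv <- render_refresh_grid(grid, "csv")
  expect_true(grepl("not_submitted", csv))
  html <- render_refresh_grid(grid, "html")
  expect_true(grepl("background", html))
})

test_that("the CLI pipeline generates, curates, gates and is deterministic", {
  dir <- withr::local_tempdir()
  dm <- file.path(dir, "dm")
  expect_identical(cdmcurate_main(c("generate", "--out", dm,
                                    "--n-patients", "150", "--seed", "5")), 0L)
  out1 <- file.path(dir, "run1")
  expect_identical(
    suppressMessages(cdmcurate_main(c("curate", "--refresh-dir", dm,
                                      "--out", out1, "--gate"))), 0L)
  expect_true(file.exists(file.path(out1, "outcome.json")))
  expect_true(file.exists(file.path(out1, "edc_report.md")))
  # determinism: curating twice yields byte-identical outcome JSON
  out2 <- file.path(dir, "run2")
  suppressMessages(cdmcurate_main(c("curate", "--refresh-dir", dm,
                                    "--out", out2)))
  expect_identical(readLines(file.path(out1, "outcome.json")),
                   readLines(file.path(out2, "outcome.json")))

  # a required-check exception makes --gate exit non-zero
  unlink(file.path(dm, "DEMOGRAPHIC.csv"))
  out3 <- file.path(dir, "run3")
  expect_identical(
    suppressMessages(cdmcurate_main(c("curate", "--refresh-dir", dm,
                                      "--out", out3, "--gate"))), 1L)

  # user errors return a usage status, never a traceback
  expect_identical(suppressMessages(cdmcurate_main(c("curate"))), 2L)
  expect_identical(suppressMessages(cdmcurate_main(character(0))), 2L)
  expect_identical(suppressMessages(cdmcurate_main(c("frobnicate"))), 2L)
})

test_that("outcome JSON survives a write/read cycle for network rollups", {
  outcome <- clean_outcome()
  path <- withr::local_tempfile(fileext = ".json")
  write_outcome_json(outcome, path)
  back <- read_outcome_json(path)
  expect_identical(back$datamart_id, outcome$datamart_id)
  expect_identical(back$investigative_exceptions, outcome$investigative_exceptions)
  expect_equal(back$check_results$exception, outcome$check_results$exception)
})
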