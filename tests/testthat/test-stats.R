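# curation_stats: lookback windowing, frequencies, crosstabs, field
# summaries, volume series.

test_that("lookback retains the window, missing dates, and active patients", {
  refresh_date <- as.Date("2024-12-31")
  dx_dates <- c(rep(as.Date("2020-06-01"), 30),       # in window
                rep(as.Date("2013-06-01"), 5))        # 11 years back
  r <- tiny_refresh(refresh_date, admit = as.Date("2020-06-01"),
                    dx_date = dx_dates)
  w <- apply_lookback(r, test_schema(), years = 10)
  expect_identical(nrow(w$tables$DIAGNOSIS), 30L)

  # boundary day itself is retained (closed window)
  r2 <- tiny_refresh(refresh_date, admit = c(as.Date("2014-12-31"),
                                             as.Date("2014-12-30")))
  w2 <- apply_lookback(r2, test_schema(), years = 10)
  expect_identical(w2$tables$ENCOUNTER$ADMIT_DATE, as.Date("2014-12-31"))

  # missing dates are retained and accounted for
  r3 <- tiny_refresh(refresh_date, admit = as.Date(c("2020-01-01", NA)))
  w3 <- apply_lookback(r3, test_schema(), years = 10)
  expect_identical(nrow(w3$tables$ENCOUNTER), 2L)
  acct <- attr(w3, "lookback")
  enc_acct <- acct[acct$table == "ENCOUNTER", ]
  expect_identical(enc_acct$missing_date, 1L)
  # conservation: in + out + missing = original rows
  expect_identical(enc_acct$in_window + enc_acct$out_of_window +
                     enc_acct$missing_date, 2L)

  # patients with no retained record drop out of DEMOGRAPHIC
  r4 <- tiny_refresh(refresh_date, admit = as.Date("2013-01-01"))
  w4 <- apply_lookback(r4, test_schema(), years = 10)
  expect_identical(nrow(w4$tables$DEMOGRAPHIC), 0L)
})

test_that("field frequencies: identity, empty, and mix recovery", {
  r <- tiny_refresh(admit = rep(as.Date("2024-06-01"), 5))
  ft <- field_frequencies(r, "ENCOUNTER", "ENC_TYPE")
  expect_identical(ft$rows$value, "IP")
  expect_identical(ft$rows$count, 5L)
  expect_equal(ft$rows$percent, 100)

  r0 <- generate_datamart(population_config(n_patients = 0, seed = 1))
  ft0 <- field_frequencies(r0, "ENCOUNTER", "ENC_TYPE")
  expect_identical(ft0$total, 0L)
  expect_identical(nrow(ft0$rows), 0L)
  expect_error(field_frequencies(r, "ENCOUNTER", "NOPE"), "unknown field")

  # generator parameter recovery: enc_type mix within ~4 binomial sd
  mix <- c(AV = 0.7, IP = 0.3)
  big <- generate_datamart(population_config(n_patients = 400, seed = 55,
                                             enc_type_mix = mix))
  ftb <- field_frequencies(big, "ENCOUNTER", "ENC_TYPE")
  p_av <- ftb$rows$count[ftb$rows$value == "AV"] / ftb$total
  tol <- 4 * sqrt(0.7 * 0.3 / ftb$total)
  expect_lt(abs(p_av - 0.7), tol)
  # invariants: counts sum to total; percents to 100
  expect_identical(sum(ftb$rows$count), ftb$total)
  expect_lt(abs(sum(ftb$rows$percent) - 100), 0.1)
})

test_that("crosstab columns are years and marginals match frequencies", {
  r <- generate_datamart(population_config(n_patients = 60, seed = 7))
  w <- apply_lookback(r, test_schema())
  ct <- crosstab_by_year(w, test_schema(), "ENCOUNTER", "ENC_TYPE")
  expect_true(all(grepl("^\\d{4}$", ct$years)))
  ff <- field_frequencies(w, "ENCOUNTER", "ENC_TYPE")
  marg <- rowSums(ct$cells[, -1, drop = FALSE])
  names(marg) <- ct$cells$value
  expect_identical(unname(marg[ff$rows$value]), as.numeric(ff$rows$count))
})

test_that("field summaries count missing/non-missing/distinct correctly", {
  r <- tiny_refresh(admit = rep(as.Date("2024-06-01"), 4), enc_type = "AV")
  # DISCHARGE_DISPOSITION is "" for ambulatory rows: all missing
  fs <- field_summaries(r, test_schema())
  row <- fs[fs$table == "ENCOUNTER" & fs$field == "DISCHARGE_DISPOSITION", ]
  expect_identical(row$missing, 4L)
  expect_identical(row$distinct, 0L)
  # a primary key has distinct == non_missing
  pk <- fs[fs$table == "ENCOUNTER" & fs$field == "ENCOUNTERID", ]
  expect_identical(pk$distinct, pk$non_missing)
  # agreement with field_frequencies on the missing count
  big <- generate_datamart(population_config(n_patients = 80, seed = 3),
                           error_profile(missing_field_rates =
                             list(PRESCRIBING.RX_DAYS_SUPPLY = 0.4)))
  fsb <- field_summaries(big, test_schema())
  miss <- fsb$missing[fsb$table == "PRESCRIBING" & fsb$field == "RX_DAYS_SUPPLY"]
  ff <- field_frequencies(big, "PRESCRIBING", "RX_DAYS_SUPPLY")
  expect_identical(miss, sum(ff$rows$count[ff$rows$value == ""]))
  expect_identical(miss, sum(big$audit$defect == "missing_value" &
                               big$audit$field == "RX_DAYS_SUPPLY"))
})

test_that("volume series buckets are contiguous and conserve counts", {
  r <- generate_datamart(population_config(n_patients = 120, seed = 19))
  w <- apply_lookback(r, test_schema())
  vs <- volume_series(w, test_schema(), "ENCOUNTER")
  enc <- w$tables$ENCOUNTER
  in_window <- sum(!is.na(enc$ADMIT_DATE) & enc$ADMIT_DATE <= w$refresh_date)
  expect_identical(sum(vs$counts), in_window)
  expect_identical(length(vs$months), length(vs$counts))
  # near-uniform buckets for an (almost) constant-rate generator
  flat <- generate_datamart(population_config(n_patients = 300, seed = 19,
                                              growth = 0, seasonal_amp = 0))
  vsf <- volume_series(apply_lookback(flat, test_schema()), test_schema(),
                       "ENCOUNTER")
  p <- suppressWarnings(chisq.test(vsf$counts)$p.value)
  expect_gt(p, 1e-6)

  # empty table: a single zero bucket at the refresh month
  r0 <- generate_datamart(population_config(n_patients = 0, seed = 1))
  vs0 <- volume_series(r0, test_schema(), "ENCOUNTER")
  expect_true(all(vs0$counts == 0))
})

test_that("curation stats export as tidy CSV files", {
  r <- generate_datamart(population_config(n_patients = 30, seed = 2))
  dir <- withr::local_tempdir()
  files <- write_curation_stats(apply_lookback(r, test_schema()),
                                test_schema(), dir)
  expect_true(all(file.exists(files)))
  fs <- read.csv(file.path(dir, "field_summaries.csv"))
  expect_true(all(c("table", "field", "missing", "non_missing", "distinct")
                  %in% names(fs)))
})
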