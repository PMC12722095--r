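# checks_catalog: boundary conventions and behavior of the individual
# check rules on hand-built fixtures.

check_of <- function(id) test_catalog()$checks[[id]]

test_that("future-date boundary: the refresh date itself is not future", {
  rd <- as.Date("2024-12-31")
  r <- tiny_refresh(rd, admit = c(rd, rd - 1, rd + 1))
  res <- evaluate_check(check_of("DC2.01"), r, NULL, test_schema())
  adm <- res[res$table == "ENCOUNTER" & res$field == "ADMIT_DATE", ]
  expect_identical(adm$numerator, 1)
  expect_identical(adm$denominator, 3)
})

test_that("illogical-date window is closed at admit - W exactly", {
  admit <- as.Date("2024-06-10")
  w <- check_of("DC2.03")$params$window_days
  r <- tiny_refresh(admit = admit, px_date = c(admit - w, admit - w - 1))
  res <- evaluate_check(check_of("DC2.03"), r, NULL, test_schema())
  px <- res[res$table == "PROCEDURES", ]
  expect_identical(px$numerator, 1)        # only the date beyond the window
  # discharge before admit
  r2 <- tiny_refresh(admit = admit, discharge = admit - 3)
  res2 <- evaluate_check(check_of("DC2.03"), r2, NULL, test_schema())
  dis <- res2[res2$qualifier == "discharge-before-admit", ]
  expect_identical(dis$numerator, 1)
  # fully consistent dates: no exceptions anywhere
  r3 <- tiny_refresh(admit = admit, discharge = admit + 2,
                     dx_date = admit, px_date = admit + 1)
  res3 <- evaluate_check(check_of("DC2.03"), r3, NULL, test_schema())
  expect_true(all(res3$status != "exception"))
})

test_that("plausible ranges are closed intervals", {
  r <- tiny_refresh(admit = rep(as.Date("2024-06-01"), 3))
  r$tables$VITAL <- data.frame(
    VITALID = c("V1", "V2", "V3"), PATID = "P001", ENCOUNTERID = "E001",
    MEASURE_DATE = as.Date("2024-06-01"),
    HT = 65, WT = 150, SYSTOLIC = c(260, 261, 400), DIASTOLIC = 80,
    stringsAsFactors = FALSE)
  res <- evaluate_check(check_of("DC2.02"), r, NULL, test_schema())
  sys <- res[res$field == "SYSTOLIC", ]
  expect_identical(sys$numerator, 2)       # 260 is inside the closed bound
  expect_identical(sys$denominator, 3)
})

test_that("ratio checks recover generator means and flag forced bands", {
  r <- generate_datamart(population_config(n_patients = 200, seed = 41,
                                           diagnoses_per_encounter = 2))
  w <- apply_lookback(r, test_schema())
  res <- evaluate_check(check_of("DC3.01"), w, NULL, test_schema())
  overall <- res$value[res$qualifier == "overall"]
  expect_lt(abs(overall - 2), 0.15)        # sampling error around the mean
  expect_true(all(res$status[res$qualifier == "overall"] == "pass"))

  # a band excluding the true ratio forces an exception
  forced <- check_of("DC3.01")
  forced$threshold <- threshold("ratio", "between", 5, value_high = 10)
  resf <- evaluate_check(forced, w, NULL, test_schema())
  expect_identical(resf$status[resf$qualifier == "overall"], "exception")

  # encounters per visit sits at 1 for collision-free data
  res24 <- evaluate_check(check_of("DC2.04"), w, NULL, test_schema())
  expect_gte(res24$value, 1)
  expect_identical(res24$status, "pass")
})

test_that("principal-diagnosis rule scopes to inpatient encounters", {
  admit <- as.Date("2024-06-01")
  r <- tiny_refresh(admit = admit, enc_type = "IP", dx_date = admit)
  res <- evaluate_check(check_of("DC2.07"), r, NULL, test_schema())
  expect_identical(res$numerator, 0)
  r$tables$DIAGNOSIS$PDX <- "S"            # principal flag omitted entirely
  res2 <- evaluate_check(check_of("DC2.07"), r, NULL, test_schema())
  expect_identical(res2$proportion, 1)
  # no inpatient encounters -> not applicable
  r3 <- tiny_refresh(admit = admit, enc_type = "AV", dx_date = admit)
  res3 <- evaluate_check(check_of("DC2.07"), r3, NULL, test_schema())
  expect_identical(res3$status, "not_applicable")
})

test_that("volume outlier detector flags dips and is scale invariant", {
  flat <- rep(1000L, 36)
  fl <- cdmcurate:::flag_volume_outliers(flat, 0.25, 4)
  expect_identical(fl$flagged, 0L)
  gap <- flat; gap[13:15] <- 0L
  fl2 <- cdmcurate:::flag_volume_outliers(gap, 0.25, 4)
  expect_identical(fl2$months, 13:15)
  # uniform rescaling changes nothing
  fl3 <- cdmcurate:::flag_volume_outliers(gap * 2L, 0.25, 4)
  expect_identical(fl3$months, fl2$months)
  # too-short series is not applicable at the measure level
  short <- tiny_refresh(admit = as.Date("2024-06-01"))
  res <- evaluate_check(check_of("DC2.08"), short, NULL, test_schema())
  expect_true(all(res$status %in% c("not_applicable")))
})

test_that("latency counts whole months back to the last complete month", {
  # counts complete through the refresh month -> latency 0
  expect_identical(cdmcurate:::compute_latency(rep(100, 24)), 0)
  # data stops 5 months before the refresh month
  stopped <- c(rep(100, 19), rep(0, 5))
  expect_identical(cdmcurate:::compute_latency(stopped), 5)
  # exactly 50% of the preceding median still counts as complete
  half <- c(rep(100, 23), 50)
  expect_identical(cdmcurate:::compute_latency(half), 0)
  just_under <- c(rep(100, 23), 49)
  expect_identical(cdmcurate:::compute_latency(just_under), 1)

  # end-to-end: a generator that stops encounters 5 months early
  pop <- population_config(n_patients = 150, seed = 61,
                           date_range = as.Date(c("2022-01-01", "2024-07-31")))
  r <- generate_datamart(pop, refresh_date = as.Date("2024-12-31"))
  res <- evaluate_check(check_of("DC3.07"), apply_lookback(r, test_schema()),
                        NULL, test_schema())
  expect_identical(res$value, 5)
  expect_identical(res$status, "exception")   # beyond the 3-month threshold
})

test_that("persistence rules pass on duplicated histories, flag real drops", {
  pop <- population_config(n_patients = 100, seed = 71)
  r <- generate_datamart(pop)
  r2 <- r; r2$refresh_ordinal <- 2L; r2$refresh_date <- r$refresh_date + 90
  for (id in c("DC4.01", "DC4.02", "DC4.03")) {
    res <- evaluate_check(check_of(id), apply_lookback(r2, test_schema()),
                          list(r), test_schema())
    expect_true(all(res$status != "exception"), info = id)
  }
  # no history at all -> all measures not applicable
  res0 <- evaluate_check(check_of("DC4.01"), apply_lookback(r, test_schema()),
                         NULL, test_schema())
  expect_true(all(res0$status == "not_applicable"))

  # a 20% record drop in one table trips DC4.01 there
  shrunk <- r2
  enc <- shrunk$tables$ENCOUNTER
  shrunk$tables$ENCOUNTER <- enc[seq_len(floor(0.8 * nrow(enc))), ]
  res4 <- evaluate_check(check_of("DC4.01"), apply_lookback(shrunk, test_schema()),
                         list(r), test_schema())
  expect_identical(res4$status[res4$table == "ENCOUNTER"], "exception")

  # a closed-year drop trips DC4.03 for that year only
  r3 <- r2
  dx <- r3$tables$DIAGNOSIS
  in_2022 <- format(dx$DX_DATE, "%Y") == "2022"
  drop <- which(in_2022)[seq_len(floor(0.2 * sum(in_2022)))]
  r3$tables$DIAGNOSIS <- dx[-drop, ]
  res5 <- evaluate_check(check_of("DC4.03"), apply_lookback(r3, test_schema()),
                         list(r), test_schema())
  dx_rows <- res5[res5$table == "DIAGNOSIS" & !is.na(res5$value), ]
  expect_identical(dx_rows$status[dx_rows$qualifier == "2022"], "exception")
  expect_true(all(dx_rows$status[dx_rows$qualifier != "2022"] == "pass"))
})

test_that("terminology mapping rules accept preferred codes and valid units", {
  r <- generate_datamart(population_config(n_patients = 80, seed = 81))
  w <- apply_lookback(r, test_schema())
  for (id in c("DC3.08", "DC3.09", "DC3.12")) {
    res <- evaluate_check(check_of(id), w, NULL, test_schema())
    expect_identical(res$numerator, 0, info = id)
  }
  # an ingredient-level RxNorm code is not a preferred term type
  w$tables$PRESCRIBING$RXNORM_CUI[1] <- "6809"   # metformin, TTY=IN
  res8 <- evaluate_check(check_of("DC3.08"), w, NULL, test_schema())
  expect_identical(res8$numerator, 1)
  # mg/dL and mmol/L both count as valid units; empty does not
  w$tables$LAB_RESULT_CM$RESULT_UNIT[1:2] <- c("mmol/L", "")
  res12 <- evaluate_check(check_of("DC3.12"), w, NULL, test_schema())
  expect_identical(res12$numerator, 1)
})
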