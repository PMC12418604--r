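test_that("qualifier filter keeps confirmed outpatient and admission/primary/secondary inpatient", {
  d <- dplyr::bind_rows(
    raw_record("P1", "F10.2", "outpatient", "suspecting"),
    raw_record("P2", "K70.3", "inpatient", "secondary"),
    raw_record("P3", "R78.0", "outpatient", "confirmed"),
    raw_record("P4", "F10.1", "outpatient", "confirmed"),
    raw_record("P5", "F10.3", "inpatient", "surgery"),
    raw_record("P6", "O35.4", "inpatient", "primary")
  )
  kept <- filter_diagnoses(d)
  expect_setequal(kept$person_id, c("P2", "P4"))
  log <- attr(kept, "drop_log")
  expect_equal(sum(log$n) + nrow(kept), nrow(d))
  expect_equal(log$n[log$reason == "excluded_code"], 2L)
  expect_equal(log$n[log$reason == "non_qualifying_qualifier"], 2L)
})

test_that("unknown qualifiers are dropped with a warning, not an error", {
  d <- dplyr::bind_rows(
    raw_record("P1", "F10.2", "outpatient", "zustand_nach"),
    raw_record("P2", "F10.2", "outpatient", "confirmed")
  )
  expect_warning(kept <- filter_diagnoses(d), "unknown qualifier")
  expect_equal(kept$person_id, "P2")
  log <- attr(kept, "drop_log")
  expect_equal(log$n[log$reason == "unknown_qualifier"], 1L)
})

test_that("quarter median day matches day-enumeration oracle for all quarters", {
  # frozen worked examples: earlier middle day of even-length quarters
  expect_equal(quarter_median_day(2017, 1), as.Date("2017-02-14"))
  expect_equal(quarter_median_day(2020, 1), as.Date("2020-02-15"))

  for (y in 2017:2021) {
    for (q in 1:4) {
      start <- as.Date(sprintf("%d-%02d-01", y, 3 * (q - 1) + 1))
      stop <- seq(start, by = "3 months", length.out = 2)[2] - 1
      days <- seq(start, stop, by = "day")
      n <- length(days)
      oracle <- if (n %% 2 == 0) days[n / 2] else days[(n + 1) / 2]
      expect_equal(quarter_median_day(y, q), oracle)
    }
  }
  expect_error(quarter_median_day(2019, 5), "1\\.\\.4")
})

test_that("dates come from the quarter median (outpatient) or admission day (inpatient)", {
  d <- dplyr::bind_rows(
    raw_record("P1", "F10.2", "outpatient", "confirmed", 2019, quarter = 3),
    raw_record("P2", "F10.2", "inpatient", "primary", 2019,
               admission_date = as.Date("2019-06-03"),
               discharge_date = as.Date("2019-06-10"))
  )
  dated <- assign_dates(d)
  expect_equal(dated$assigned_date[1], quarter_median_day(2019, 3))
  expect_equal(dated$assigned_date[2], as.Date("2019-06-03"))

  bad <- raw_record("P1", quarter = 7)
  expect_error(assign_dates(bad), "quarter")
})

test_that("classification returns the overlapping level set of the period", {
  d <- dplyr::bind_rows(
    raw_record("P1", "F10.2", year = 2019),
    raw_record("P1", "F10.3", year = 2019)
  )
  cls <- classify_severity(assign_dates(d))
  expect_equal(cls$level, c(3L, 4L))

  expect_equal(nrow(classify_severity(assign_dates(raw_record()[0, ]))), 0L)

  d2 <- purrr::map_dfr(c("F10.0", "T51.9", "K70.3", "G62.1"),
                       function(cc) raw_record("P9", cc, year = 2018))
  cls2 <- classify_severity(assign_dates(d2))
  expect_equal(cls2$level, oracle_levels(c("F10.0", "T51.9", "K70.3",
                                           "G62.1")))
  expect_equal(cls2$level, c(1L, 5L))
})

test_that("classifier agrees with brute-force set membership on random multisets", {
  universe <- c(severity_code_map()$code, excluded_codes(),
                "I10", "J44.9", "F32.9", "E11.4", "K52.9", "Z99.9")
  set.seed(42)
  for (i in 1:500) {
    codes <- sample(universe, sample(1:20, 1), replace = TRUE)
    d <- purrr::map_dfr(codes, function(cc) raw_record("PX", cc, year = 2020))
    got <- classify_severity(assign_dates(filter_diagnoses(d)))$level
    expect_equal(got, oracle_levels(setdiff(codes, excluded_codes())))
  }
})

test_that("adding a qualifying diagnosis never removes a level (monotonicity)", {
  set.seed(7)
  universe <- severity_code_map()$code
  for (i in 1:50) {
    base_codes <- sample(universe, sample(1:5, 1))
    extra <- sample(universe, 1)
    d1 <- purrr::map_dfr(base_codes, function(cc) raw_record("P", cc))
    d2 <- dplyr::bind_rows(d1, raw_record("P", extra))
    l1 <- classify_severity(assign_dates(d1))$level
    l2 <- classify_severity(assign_dates(d2))$level
    expect_true(all(l1 %in% l2))
  }
})

test_that("filtering commutes with classification", {
  d <- dplyr::bind_rows(
    raw_record("P1", "F10.2", "outpatient", "confirmed"),
    raw_record("P1", "K70.0", "outpatient", "suspecting"),
    raw_record("P1", "F10.1", "inpatient", "admission"),
    raw_record("P1", "F10.4", "inpatient", "follow_up")
  )
  a <- classify_severity(assign_dates(filter_diagnoses(d)))
  pre <- d[c(1, 3), ] # records known to qualify
  b <- classify_severity(assign_dates(pre))
  expect_equal(a, b)
  expect_equal(a$level, c(2L, 3L))
})

test_that("level-5 composition partitions members exhaustively", {
  # degenerate: only K70 codes
  d <- dplyr::bind_rows(
    raw_record("P1", "K70.0"), raw_record("P2", "K70.3")
  )
  comp <- level5_composition(assign_dates(d))
  expect_equal(comp$share[comp$group == "k70_only"], 1)
  expect_equal(sum(comp$share), 1)

  # combination counts only in the combination bucket
  d2 <- dplyr::bind_rows(
    raw_record("P1", "K70.3"), raw_record("P1", "G62.1"),
    raw_record("P2", "F10.6")
  )
  comp2 <- level5_composition(assign_dates(d2))
  expect_equal(comp2$n[comp2$group == "combination_or_other"], 1L)
  expect_equal(comp2$n[comp2$group == "f10_59_only"], 1L)
  expect_equal(comp2$n[comp2$group == "k70_only"], 0L)
  expect_equal(sum(comp2$n), 2L)
  expect_equal(sum(comp2$share), 1)
})
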