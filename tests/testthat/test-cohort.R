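# the worked subsample example: level 3 every year 2017-2021, level 4 in
# 2019 and 2021
worked_example_classified <- function() {
  dplyr::bind_rows(
    tibble::tibble(person_id = "P1", year = 2017:2021, level = 3L),
    tibble::tibble(person_id = "P1", year = c(2019L, 2021L), level = 4L)
  )
}

test_that("subsample 1 keeps the first year of each severity level", {
  cls <- worked_example_classified()
  py <- build_person_years(hand_person(), full_coverage(), cls, 2017:2021)
  ss1 <- build_subsample1(py, cls)
  lvl_years <- ss1[ss1$severity_level > 0, c("severity_level", "year")]
  expect_equal(lvl_years$severity_level, c(3L, 4L))
  expect_equal(lvl_years$year, c(2017L, 2019L))
  # level-0 row uses the first year with any AUD
  expect_equal(ss1$year[ss1$severity_level == 0], 2017L)
})

test_that("subsample 2 keeps the annual maximum severity level", {
  cls <- worked_example_classified()
  py <- build_person_years(hand_person(), full_coverage(), cls, 2017:2021)
  ss2 <- build_subsample2(py, cls)
  expect_equal(ss2$year, 2017:2021)
  expect_equal(ss2$max_severity_level, c(3L, 3L, 4L, 3L, 4L))
})

test_that("a year without any AUD diagnosis contributes no subsample-2 row", {
  cls <- tibble::tibble(person_id = "P1", year = c(2017L, 2019L),
                        level = c(2L, 1L))
  py <- build_person_years(hand_person(), full_coverage(), cls, 2017:2021)
  ss2 <- build_subsample2(py, cls)
  expect_equal(ss2$year, c(2017L, 2019L))
  # single diagnosis yields one level row plus the level-0 row, same year
  cls1 <- tibble::tibble(person_id = "P2", year = 2018L, level = 4L)
  py1 <- build_person_years(hand_person("P2"), full_coverage("P2"), cls1,
                            2017:2021)
  ss1 <- build_subsample1(py1, cls1)
  expect_equal(nrow(ss1), 2L)
  expect_setequal(ss1$severity_level, c(0L, 4L))
  expect_equal(unique(ss1$year), 2018L)
})

test_that("counting oracle: full design gives 15 person-years and 75 observations", {
  persons <- hand_person(c("A", "B", "C"))
  coverage <- full_coverage(c("A", "B", "C"))
  cls <- tidyr::expand_grid(person_id = c("A", "B", "C"),
                            year = 2017:2021, level = 1:5)
  py <- build_person_years(persons, coverage, cls, 2017:2021)
  expect_equal(nrow(py), 15L)
  eligible <- dplyr::inner_join(cls, py[, c("person_id", "year")],
                                by = c("person_id", "year"))
  expect_equal(nrow(eligible), 75L)
  ss1 <- build_subsample1(py, cls)
  expect_equal(nrow(ss1), 3 * 6) # 5 levels + level 0 per person
  # all five levels first observed in distinct years -> distinct rows
  cls_d <- tibble::tibble(person_id = "D", year = 2017:2021, level = 1:5)
  py_d <- build_person_years(hand_person("D"), full_coverage("D"), cls_d,
                             2017:2021)
  ss1_d <- build_subsample1(py_d, cls_d)
  expect_equal(ss1_d$year[ss1_d$severity_level > 0], 2017:2021)
})

test_that("coverage gates inclusion: one insured day suffices, none excludes", {
  persons <- hand_person(c("P1", "P2"))
  coverage <- tibble::tibble(
    person_id = c("P1", "P2"),
    start_date = as.Date(c("2018-12-31", "2017-01-01")),
    end_date = as.Date(c("2018-12-31", "2017-12-31"))
  )
  cls <- tibble::tibble(person_id = c("P1", "P2"), year = 2018L, level = 2L)
  py <- build_person_years(persons, coverage, cls, 2017:2021)
  expect_equal(py$person_id[py$any_aud], "P1")
  expect_equal(py$insured_days[py$person_id == "P1"], 1L)
  # P2's 2018 diagnosis has no 2018 coverage
  expect_false(any(py$person_id == "P2" & py$year == 2018))
  expect_equal(attr(py, "dropped_no_coverage"), 1L)
})

test_that("employment resolution follows most-days with hierarchical tie-break", {
  sp <- tibble::tibble(
    person_id = "P1", status = c("employed", "unemployed"),
    start_date = as.Date(c("2019-01-01", "2019-10-28")),
    end_date = as.Date(c("2019-10-27", "2019-12-31"))
  ) # 300 days employed, 65 unemployed
  out <- resolve_employment(sp, 2019)
  expect_equal(out$employment, "employed")

  # 150 unemployed, 150 retired, 65 other: tie broken by hierarchy
  sp2 <- tibble::tibble(
    person_id = "P2", status = c("unemployed", "retired", "other"),
    start_date = as.Date(c("2019-01-01", "2019-05-31", "2019-10-28")),
    end_date = as.Date(c("2019-05-30", "2019-10-27", "2019-12-31"))
  )
  expect_equal(as.numeric(sp2$end_date - sp2$start_date) + 1, c(150, 150, 65))
  expect_equal(resolve_employment(sp2, 2019)$employment, "unemployed")

  # no spells at all: the person-year defaults to "other"
  py <- build_person_years(hand_person(), full_coverage(),
                           tibble::tibble(person_id = "P1", year = 2018L,
                                          level = 1L),
                           2017:2021,
                           employment_spells = sp[0, ])
  expect_true(all(py$employment == "other"))

  # a year not covered by any spell resolves to "other"
  out3 <- resolve_employment(sp, c(2019, 2020))
  expect_equal(out3$employment[out3$year == 2020], "other")
})

test_that("overlapping spells with different statuses are rejected", {
  sp <- tibble::tibble(
    person_id = "P1", status = c("employed", "retired"),
    start_date = as.Date(c("2019-01-01", "2019-06-01")),
    end_date = as.Date(c("2019-08-01", "2019-12-31"))
  )
  expect_error(resolve_employment(sp, 2019), "overlapping")
})

test_that("subsample sizes and conservation invariants hold on simulated data", {
  cfg <- small_config(seed = 31)
  sim <- simulate_claims(cfg)
  cls <- classify_severity(assign_dates(filter_diagnoses(sim$diagnoses)))
  py <- build_person_years(sim$persons, sim$coverage_spells, cls, cfg$years,
                           sim$employment_spells)
  ss1 <- build_subsample1(py, cls)
  ss2 <- build_subsample2(py, cls)

  per1 <- dplyr::count(ss1, person_id)
  expect_lte(max(per1$n), 6L) # 5 levels + level-0 row
  per2 <- dplyr::count(ss2, person_id)
  expect_lte(max(per2$n), length(cfg$years))

  # every study person appears in both subsamples
  study <- unique(py$person_id[py$any_aud])
  expect_setequal(study, unique(ss1$person_id))
  expect_setequal(study, unique(ss2$person_id))

  # subsample-2 level is never below any same-year subsample-1 level
  joined <- dplyr::inner_join(
    ss1[ss1$severity_level > 0, c("person_id", "year", "severity_level")],
    ss2[, c("person_id", "year", "max_severity_level")],
    by = c("person_id", "year")
  )
  expect_true(all(joined$max_severity_level >= joined$severity_level))
})
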