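test_that("a fixed seed yields identical output; empty config yields empty tables", {
  cfg <- small_config(seed = 5, n_persons = 300, insured_pool_size = 1500)
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$coverage_spells, b$coverage_spells)
  expect_identical(a$employment_spells, b$employment_spells)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_identical(a$truth$person_year_levels, b$truth$person_year_levels)

  empty <- simulate_claims(small_config(n_persons = 0,
                                        insured_pool_size = 0))
  expect_equal(nrow(empty$persons), 0L)
  expect_equal(nrow(empty$diagnoses), 0L)
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(prevalence_by_level = c(`1` = 0.5, `2` = 0.013,
                                                  `3` = 0.015, `4` = 0.002,
                                                  `5` = 0.007)),
               "prevalence_by_level")
  expect_error(sim_config(n_persons = 500, insured_pool_size = 100000),
               "n_persons")
  expect_error(sim_config(target_within_person_corr = 1.2),
               "target_within_person_corr")
  expect_error(sim_config(employment_dist = c(employed = 1, unemployed = 1,
                                              retired = 0, other = 0)),
               "employment_dist")
})

test_that("every person is insured in every study year (denominator conservation)", {
  cfg <- small_config(seed = 8, n_persons = 200, insured_pool_size = 1000,
                      partial_coverage_frac = 0.5)
  sim <- simulate_claims(cfg)
  counts <- insured_counts(sim$coverage_spells, cfg$years)
  expect_equal(counts$n_insured, rep(1000L, length(cfg$years)))
  # partial spells still start in the first and end in the last year
  expect_true(all(sim$coverage_spells$start_date <= as.Date("2017-12-31")))
  expect_true(all(sim$coverage_spells$end_date >= as.Date("2021-01-01")))
})

test_that("the classifier recovers the planted severity sets exactly", {
  cfg <- small_config(seed = 21)
  sim <- simulate_claims(cfg)
  cls <- classify_severity(assign_dates(filter_diagnoses(sim$diagnoses)))
  expect_identical(
    as.data.frame(cls),
    as.data.frame(sim$truth$person_year_levels)
  )
})

test_that("noise qualifiers stay below the observed dialect shares", {
  cfg <- small_config(seed = 22)
  sim <- simulate_claims(cfg)
  map <- severity_code_map()
  alc <- sim$diagnoses[sim$diagnoses$icd_code %in% map$code, ]
  outp <- alc[alc$setting == "outpatient", ]
  inp <- alc[alc$setting == "inpatient", ]
  expect_lt(mean(outp$qualifier != "confirmed"), 0.10)
  expect_lt(mean(!inp$qualifier %in% c("admission", "primary", "secondary")),
            0.04)
  # outpatient records carry quarters, inpatient records carry dates
  expect_true(all(!is.na(outp$quarter)))
  expect_true(all(is.na(outp$admission_date)))
  expect_true(all(is.na(inp$quarter)))
  expect_true(all(!is.na(inp$admission_date)))
  expect_true(all(inp$admission_date <= inp$discharge_date))
})

test_that("degenerate overlap mode plants exactly one level per case-year", {
  cfg <- small_config(seed = 23, overlap_structure = "none")
  sim <- simulate_claims(cfg)
  per_py <- dplyr::count(sim$truth$person_year_levels, person_id, year)
  expect_true(all(per_py$n == 1L))
  # and the classifier sees exactly one level per person-year
  cls <- classify_severity(assign_dates(filter_diagnoses(sim$diagnoses)))
  expect_true(all(dplyr::count(cls, person_id, year)$n == 1L))
})

test_that("planted level-4 years carry a dependence code per the containment default", {
  cfg <- small_config(seed = 24, n_persons = 2000,
                      insured_pool_size = 10000)
  tr <- simulate_claims(cfg)$truth$person_year_levels
  wide <- tidyr::pivot_wider(dplyr::mutate(tr, v = TRUE),
                             names_from = level, values_from = v,
                             names_prefix = "l", values_fill = FALSE)
  l4 <- wide[wide$l4, ]
  expect_gt(mean(l4$l3), 0.8) # default containment 0.9
})

test_that("zero frailty with null effects gives near-zero within-person correlation", {
  cfg <- small_config(seed = 25, n_persons = 5000,
                      insured_pool_size = 25000, frailty_var = 0,
                      severity_log_rr = c(`2` = 0, `3` = 0, `4` = 0,
                                          `5` = 0))
  sim <- simulate_claims(cfg)
  cls <- classify_severity(assign_dates(filter_diagnoses(sim$diagnoses)))
  py <- build_person_years(sim$persons, sim$coverage_spells, cls, cfg$years,
                           sim$employment_spells)
  ss2 <- build_subsample2(py, cls) |>
    dplyr::left_join(ecs_score(assign_dates(filter_diagnoses(sim$diagnoses))),
                     by = c("person_id", "year")) |>
    dplyr::mutate(ecs = dplyr::coalesce(ecs_total, 0L))
  fit <- fit_severity_gee(ss2)
  # MC standard error of an exchangeable correlation over ~n pairs
  pairs <- sum(choose(table(ss2$person_id), 2))
  expect_lt(abs(fit$rho), 3 / sqrt(pairs))
})

test_that("planted truth reports the generating parameters", {
  cfg <- small_config()
  tr <- planted_truth(cfg)
  expect_equal(unname(tr$params$severity_log_rr["5"]), log(1.65))
  expect_equal(unname(tr$params$prevalence_by_level["3"]), 0.015)
  expect_equal(tr$params$target_within_person_corr, 0.708)
  expect_equal(unname(tr$params$ecs_mean_by_level["5"]), 3.5 * 1.65)

  sim <- simulate_claims(cfg)
  tr2 <- planted_truth(sim)
  expect_equal(tr2$params$severity_log_rr, cfg$severity_log_rr)
  expect_true(all(c("person_id", "year", "level") %in%
                    names(tr2$person_year_levels)))
})

test_that("level-5 signature composition matches the planted distribution", {
  cfg <- small_config(seed = 26, n_persons = 4000,
                      insured_pool_size = 20000)
  sim <- simulate_claims(cfg)
  dated <- assign_dates(filter_diagnoses(sim$diagnoses))
  comp <- level5_composition(dated)
  n5 <- sum(comp$n)
  expect_gt(n5, 200)
  planted <- cfg$level5_signature_dist
  got <- setNames(comp$share, comp$group)
  for (g in c("k70_only", "f10_59_only", "g62_only")) {
    se <- sqrt(planted[[g]] * (1 - planted[[g]]) / n5)
    expect_lt(abs(got[[g]] - planted[[g]]), 4 * se)
  }
})

test_that("simulated tables round-trip through CSV", {
  sim <- simulate_claims(small_config(seed = 6, n_persons = 100,
                                      insured_pool_size = 500))
  dir <- withr::local_tempdir()
  paths <- write_sim_tables(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["diagnoses"]], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sim$diagnoses))
})
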