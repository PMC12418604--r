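test_that("Wilson intervals behave at the boundaries", {
  ci <- wilson_ci(c(29, 0, 1000), c(1000, 1000, 1000))
  expect_equal(ci$estimate, c(0.029, 0, 1))
  expect_equal(ci$ci_low[2], 0)
  expect_equal(ci$ci_high[3], 1)
  expect_true(all(ci$ci_low <= ci$estimate & ci$estimate <= ci$ci_high))
  expect_error(wilson_ci(1, 0), "positive")
})

test_that("annual prevalence divides classified cases by insured persons", {
  coverage <- full_coverage(sprintf("P%03d", 1:1000), years = 2020)
  cls <- tibble::tibble(person_id = sprintf("P%03d", 1:29),
                        year = 2020L, level = 3L)
  prev <- annual_prevalence(cls, coverage, years = 2020)
  p3 <- prev[prev$level == 3, ]
  expect_equal(p3$n_cases, 29L)
  expect_equal(p3$n_insured, 1000L)
  expect_equal(p3$prevalence, 0.029)
  # level 0 equals level 3 here (single level present)
  expect_equal(prev$prevalence[prev$level == 0], 0.029)
  # levels never recorded get explicit zero rows
  expect_equal(prev$n_cases[prev$level == 5], 0L)
  expect_equal(prev$ci_low[prev$level == 5], 0)

  # a year with no insured persons is an explicit error
  expect_error(annual_prevalence(cls, coverage, years = 2019:2020),
               "zero insured")
})

test_that("stratified prevalence uses stratum denominators", {
  persons <- tibble::tibble(person_id = c("A", "B", "C", "D"),
                            sex = c("male", "male", "female", "female"),
                            birth_year = 1980L)
  coverage <- full_coverage(persons$person_id, 2020)
  cls <- tibble::tibble(person_id = "A", year = 2020L, level = 2L)
  prev <- annual_prevalence(cls, coverage, persons, years = 2020,
                            strata = "sex")
  m <- prev[prev$level == 0 & prev$sex == "male", ]
  expect_equal(m$prevalence, 0.5)
  f <- prev[prev$level == 0 & prev$sex == "female", ]
  expect_equal(f$prevalence, 0)
})

test_that("average prevalence is the unweighted mean over years", {
  prev <- tibble::tibble(
    year = rep(2017:2021, 2),
    level = rep(c(0L, 3L), each = 5),
    prevalence = c(rep(0.015, 5), c(0.01, 0.02, 0.03, 0.02, 0.02))
  )
  avg <- average_prevalence(prev, 2017:2021)
  expect_equal(avg$avg_prevalence[avg$level == 0], 0.015)
  expect_equal(avg$avg_prevalence[avg$level == 3], 0.02)
  expect_error(average_prevalence(prev[prev$year != 2019, ], 2017:2021),
               "missing")
})

test_that("overlap summary counts Venn regions and cross-level shares", {
  # everyone in exactly one level: no pairwise overlap
  w1 <- tibble::tibble(person_id = c("A", "B", "C"), level = c(1L, 3L, 5L))
  ov1 <- overlap_summary(w1)
  expect_true(all(ov1$pairwise$n == 0))
  expect_equal(sum(ov1$regions$n), 3L)
  expect_true(all(ov1$share_with_other$share[c(1, 3, 5)] == 0))

  # everyone in {3, 4}: the withdrawal level is fully contained
  w2 <- tibble::tibble(person_id = rep(c("A", "B"), each = 2),
                       level = rep(c(3L, 4L), 2))
  ov2 <- overlap_summary(w2)
  expect_equal(ov2$share_with_other$share[ov2$share_with_other$level == 4], 1)
  expect_equal(ov2$pairwise$n[ov2$pairwise$level_a == 3 &
                                ov2$pairwise$level_b == 4], 2L)
  expect_equal(ov2$regions$n[ov2$regions$levels == "3+4"], 2L)
})

test_that("level-0 numerator is bounded by the level numerators (overlap identity)", {
  cfg <- small_config(seed = 77)
  sim <- simulate_claims(cfg)
  cls <- classify_severity(assign_dates(filter_diagnoses(sim$diagnoses)))
  prev <- annual_prevalence(cls, sim$coverage_spells, years = cfg$years)
  per_year <- split(prev, prev$year)
  for (p in per_year) {
    n0 <- p$n_cases[p$level == 0]
    nl <- p$n_cases[p$level > 0]
    expect_lte(n0, sum(nl) + 1e-9)
    expect_gte(n0, max(nl))
  }
})

test_that("simulated prevalence recovers the planted marginals", {
  cfg <- small_config(seed = 13, n_persons = 6000,
                      insured_pool_size = 30000)
  sim <- simulate_claims(cfg)
  cls <- classify_severity(assign_dates(filter_diagnoses(sim$diagnoses)))
  prev <- annual_prevalence(cls, sim$coverage_spells, years = cfg$years)
  # any-AUD per year within 3 binomial SDs of the planted prevalence
  for (y in cfg$years) {
    p0 <- cfg$prevalence_level0[as.character(y)]
    sd0 <- sqrt(p0 * (1 - p0) / cfg$insured_pool_size)
    got <- prev$prevalence[prev$level == 0 & prev$year == y]
    expect_lt(abs(got - p0), 3 * sd0)
  }
  # level-specific average prevalence within 3 SDs of the planted values
  avg <- average_prevalence(prev, cfg$years)
  for (l in 1:5) {
    pl <- cfg$prevalence_by_level[as.character(l)]
    sdl <- sqrt(pl * (1 - pl) / (cfg$insured_pool_size * length(cfg$years)))
    expect_lt(abs(avg$avg_prevalence[avg$level == l] - pl), 3 * sdl)
  }
})
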