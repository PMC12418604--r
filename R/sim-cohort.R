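#' Simulate the insured population: persons, coverage and employment spells
#'
#' Generates the demographic backbone of the synthetic claims data: one row
#' per insured person (the prevalence denominator), one coverage spell per
#' person guaranteeing at least one insured day in every study year, and
#' employment spells per person-year.  The first `n_persons` persons form
#' the at-risk pool from which alcohol-specific diagnoses are later drawn;
#' their demographics follow the configured case marginals (about 31%
#' female, mean age in the mid-fifties), while the remaining insured
#' persons follow a flat general-population profile.
#'
#' @param config An [sim_config()] object.
#' @return A list of tibbles: `persons` (person_id, at_risk, sex,
#'   birth_year), `coverage_spells` (person_id, start_date, end_date) and
#'   `employment_spells` (person_id, status, start_date, end_date).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "aud_sim_config"))
  withr::with_seed(derive_seed(config$seed, "cohort"), {
    n_pool <- config$insured_pool_size
    n_case <- config$n_persons
    years <- config$years
    if (n_pool == 0) {
      return(list(
        persons = tibble(person_id = character(), at_risk = logical(),
                         sex = character(), birth_year = integer()),
        coverage_spells = tibble(person_id = character(),
                                 start_date = as.Date(character()),
                                 end_date = as.Date(character())),
        employment_spells = tibble(person_id = character(),
                                   status = character(),
                                   start_date = as.Date(character()),
                                   end_date = as.Date(character()))
      ))
    }

    person_id <- sprintf("P%07d", seq_len(n_pool))
    at_risk <- seq_len(n_pool) <= n_case
    sex <- ifelse(
      runif(n_pool) < ifelse(at_risk, config$sex_female_prop, 0.5),
      "female", "male"
    )
    # ages at the first study year; at-risk persons follow the case age
    # profile, the rest of the pool a broad adult distribution
    y0 <- years[1]
    age0 <- ifelse(at_risk,
                   round(rnorm(n_pool, config$age_mean, config$age_sd)),
                   round(runif(n_pool, 18, 90)))
    age0 <- pmin(pmax(age0, 18), 99 - (max(years) - y0))
    birth_year <- as.integer(y0 - age0)
    persons <- tibble(person_id, at_risk, sex, birth_year)

    # coverage: full window by default; a configurable fraction starts late
    # in the first year and/or ends early in the last year, but every
    # person keeps >= 1 insured day in every study year
    win_start <- as.Date(sprintf("%d-01-01", min(years)))
    win_end <- as.Date(sprintf("%d-12-31", max(years)))
    partial <- runif(n_pool) < config$partial_coverage_frac
    start_off <- ifelse(partial, sample.int(364, n_pool, replace = TRUE), 0L)
    end_off <- ifelse(partial, sample.int(364, n_pool, replace = TRUE), 0L)
    coverage <- tibble(
      person_id,
      start_date = win_start + start_off,
      end_date = win_end - end_off
    )

    employment <- simulate_employment_spells(person_id, years, config)

    list(persons = persons, coverage_spells = coverage,
         employment_spells = employment)
  })
}

# Sticky annual employment states emitted as within-year spells; a fraction
# of person-years is split into two spells with a minority secondary status
# so the most-days resolution rule is exercised.
simulate_employment_spells <- function(person_id, years, config) {
  n <- length(person_id)
  statuses <- employment_levels()
  status_mat <- matrix(NA_character_, n, length(years))
  status_mat[, 1] <- sample(statuses, n, replace = TRUE,
                            prob = config$employment_dist)
  if (length(years) > 1) {
    for (j in 2:length(years)) {
      stay <- runif(n) < config$employment_sticky
      redraw <- sample(statuses, n, replace = TRUE,
                       prob = config$employment_dist)
      status_mat[, j] <- ifelse(stay, status_mat[, j - 1], redraw)
    }
  }
  py <- tibble(
    person_id = rep(person_id, times = length(years)),
    year = rep(years, each = n),
    status = as.vector(status_mat)
  )
  py$split <- runif(nrow(py)) < config$employment_split_frac
  py$sec_days <- ifelse(py$split,
                        sample(30:150, nrow(py), replace = TRUE), 0L)
  py$sec_status <- sample(statuses, nrow(py), replace = TRUE)
  # secondary status must differ; rotate when it collides
  same <- py$sec_status == py$status
  py$sec_status[same] <- statuses[(match(py$status[same], statuses)) %% 4 + 1]

  ys_lookup <- as.Date(sprintf("%d-01-01", years))
  ye_lookup <- as.Date(sprintf("%d-12-31", years))
  yi <- match(py$year, years)
  yr_start <- ys_lookup[yi]
  yr_end <- ye_lookup[yi]
  main <- tibble(person_id = py$person_id, status = py$status,
                 start_date = yr_start + py$sec_days, end_date = yr_end)
  sec <- tibble(person_id = py$person_id[py$split],
                status = py$sec_status[py$split],
                start_date = yr_start[py$split],
                end_date = yr_start[py$split] + py$sec_days[py$split] - 1)
  arrange(bind_rows(main, sec), .data$person_id, .data$start_date)
}
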