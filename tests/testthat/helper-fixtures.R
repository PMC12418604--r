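# Small simulation config for unit tests: fixed frailty variance avoids the
# pilot calibration, and a compact pool keeps runtimes low.
small_config <- function(seed = 101, ...) {
  args <- list(...)
  defaults <- list(
    n_persons = 800, insured_pool_size = 4000,
    frailty_var = 0.4, seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Build a minimal raw diagnosis record; defaults are a qualifying
# outpatient record.
raw_record <- function(person_id = "P1", icd_code = "F10.2",
                       setting = "outpatient", qualifier = "confirmed",
                       year = 2019L, quarter = 2L,
                       admission_date = as.Date(NA),
                       discharge_date = as.Date(NA)) {
  if (setting == "inpatient" && is.na(admission_date)) {
    admission_date <- as.Date(sprintf("%d-06-03", year))
    discharge_date <- admission_date + 7
    quarter <- NA_integer_
  }
  tibble::tibble(person_id, icd_code, setting, qualifier,
                 year = as.integer(year), quarter = as.integer(quarter),
                 admission_date, discharge_date)
}

# Person/coverage/classified tables for hand-built cohort tests.
hand_person <- function(id = "P1", sex = "male", birth_year = 1980L) {
  tibble::tibble(person_id = id, sex = sex, birth_year = birth_year)
}

full_coverage <- function(id = "P1", years = 2017:2021) {
  tibble::tibble(
    person_id = id,
    start_date = as.Date(sprintf("%d-01-01", min(years))),
    end_date = as.Date(sprintf("%d-12-31", max(years)))
  )
}

# brute-force severity classification oracle: set membership over the map
oracle_levels <- function(codes) {
  map <- severity_code_map()
  sort(unique(map$level[map$code %in% toupper(trimws(codes))]))
}
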