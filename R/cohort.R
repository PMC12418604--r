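#' Resolve annual employment status from employment spells
#'
#' Within each calendar year, a person's employment status is the status
#' with the most in-year days; exact ties are broken by the hierarchy
#' employed > unemployed > retired > other.  Persons without any spell in
#' a year are assigned `"other"` (the residual class covering students,
#' unknown and migrant statuses).
#'
#' @param spells Tibble with columns `person_id`, `status`, `start_date`,
#'   `end_date` (inclusive).  Overlapping spells with different statuses
#'   for the same person are a validation error.
#' @param years Integer vector of calendar years to resolve.
#' @return A tibble `person_id`, `year`, `employment` with one row per
#'   person (appearing in `spells`) per year.
#' @export
resolve_employment <- function(spells, years) {
  stopifnot(all(c("person_id", "status", "start_date", "end_date")
                %in% names(spells)))
  if (any(!spells$status %in% employment_levels())) {
    abort("resolve_employment(): unknown employment status")
  }
  if (any(spells$start_date > spells$end_date)) {
    abort("resolve_employment(): spell with start_date after end_date")
  }
  chk <- spells |>
    arrange(.data$person_id, .data$start_date) |>
    group_by(.data$person_id) |>
    mutate(overlap = .data$start_date <= lag(.data$end_date) &
             .data$status != lag(.data$status)) |>
    ungroup()
  if (any(chk$overlap, na.rm = TRUE)) {
    abort("resolve_employment(): overlapping spells with different statuses")
  }

  per_year <- purrr::map_dfr(years, function(y) {
    ys <- as.Date(sprintf("%d-01-01", y))
    ye <- as.Date(sprintf("%d-12-31", y))
    days <- as.numeric(pmin(spells$end_date, ye) -
                         pmax(spells$start_date, ys)) + 1
    keep <- days > 0
    tibble(person_id = spells$person_id[keep], year = y,
           status = spells$status[keep], days = days[keep])
  })
  hierarchy <- employment_levels()
  resolved <- per_year |>
    group_by(.data$person_id, .data$year, .data$status) |>
    summarise(days = sum(.data$days), .groups = "drop") |>
    mutate(rank = match(.data$status, hierarchy)) |>
    arrange(.data$person_id, .data$year, dplyr::desc(.data$days),
            .data$rank) |>
    distinct(.data$person_id, .data$year, .keep_all = TRUE) |>
    select("person_id", "year", employment = "status")
  # persons with no in-year spell default to "other"
  all_py <- tidyr::expand_grid(person_id = unique(spells$person_id),
                               year = as.integer(years))
  all_py |>
    left_join(resolved, by = c("person_id", "year")) |>
    mutate(employment = if_else(is.na(.data$employment), "other",
                                .data$employment))
}

# insured days per (person, year) from coverage spells; rows only where > 0
insured_days_by_year <- function(coverage, years) {
  purrr::map_dfr(years, function(y) {
    ys <- as.Date(sprintf("%d-01-01", y))
    ye <- as.Date(sprintf("%d-12-31", y))
    days <- as.numeric(pmin(coverage$end_date, ye) -
                         pmax(coverage$start_date, ys)) + 1
    keep <- days > 0
    tibble(person_id = coverage$person_id[keep], year = as.integer(y),
           insured_days = as.integer(days[keep]))
  }) |>
    group_by(.data$person_id, .data$year) |>
    summarise(insured_days = sum(.data$insured_days), .groups = "drop")
}

#' Build the person-year table of the study population
#'
#' One row per (person, year) with at least one insured day, carrying age
#' (calendar-year convention: year minus birth year), sex, resolved
#' employment, insured days and the any-AUD flag for that year.  By
#' default only persons belonging to the study population (at least one
#' qualifying alcohol-specific diagnosis in the window) are materialised;
#' set `study_only = FALSE` to keep every insured person-year.
#'
#' Person-years with a classified diagnosis but no insured day in that
#' year are excluded (coverage gate); their count is attached as the
#' `dropped_no_coverage` attribute.
#'
#' @param persons Tibble `person_id`, `sex`, `birth_year`.
#' @param coverage Coverage spells (`person_id`, `start_date`, `end_date`).
#' @param classified Long severity table from
#'   [classify_severity()] (period `"year"`).
#' @param years Study years.
#' @param employment_spells Optional employment spells; when supplied the
#'   `employment` column is resolved via [resolve_employment()], otherwise
#'   it is `"other"`.
#' @param study_only Keep only persons with at least one classified
#'   diagnosis (default `TRUE`).
#' @return Tibble `person_id`, `year`, `age`, `age_group`, `sex`,
#'   `employment`, `insured_days`, `any_aud`.
#' @export
build_person_years <- function(persons, coverage, classified, years,
                               employment_spells = NULL,
                               study_only = TRUE) {
  years <- as.integer(years)
  ins <- insured_days_by_year(coverage, years)
  if (study_only) {
    ins <- filter(ins, .data$person_id %in% unique(classified$person_id))
  }
  py <- ins |>
    inner_join(persons, by = "person_id") |>
    mutate(age = age_in_year(.data$birth_year, .data$year),
           age_group = age_group(.data$age))

  aud_years <- distinct(classified, .data$person_id, .data$year) |>
    mutate(any_aud = TRUE)
  py <- left_join(py, aud_years, by = c("person_id", "year")) |>
    mutate(any_aud = !is.na(.data$any_aud))

  if (!is.null(employment_spells)) {
    emp <- resolve_employment(
      filter(employment_spells, .data$person_id %in% unique(py$person_id)),
      years
    )
    py <- left_join(py, emp, by = c("person_id", "year"))
    py$employment <- if_else(is.na(py$employment), "other", py$employment)
  } else {
    py$employment <- "other"
  }

  dropped <- anti_join(aud_years, ins, by = c("person_id", "year"))
  out <- select(py, "person_id", "year", "age", "age_group", "sex",
                "employment", "insured_days", "any_aud")
  attr(out, "dropped_no_coverage") <- nrow(dropped)
  out
}

#' Analysis subsample 1: first year of each severity level per person
#'
#' One row per (person, severity level) ever observed, taken from the
#' first calendar year in which that level was recorded, plus one level-0
#' (any AUD) row per person from the first year with any alcohol-specific
#' diagnosis.  Covariates travel with the selected year's person-year row.
#' Used for the descriptive comparison of severity levels; a person
#' contributes at most 5 level rows (+ the level-0 row).
#'
#' @param person_years Person-year table from [build_person_years()].
#' @param classified Long severity table (period `"year"`).
#' @return Tibble with `person_id`, `severity_level` (0-5), `year` and the
#'   person-year covariates of that year.
#' @export
build_subsample1 <- function(person_years, classified) {
  eligible <- inner_join(classified,
                         select(person_years, "person_id", "year"),
                         by = c("person_id", "year"))
  lvl0 <- eligible |>
    distinct(.data$person_id, .data$year) |>
    mutate(level = 0L)
  firsts <- bind_rows(eligible, lvl0) |>
    group_by(.data$person_id, .data$level) |>
    summarise(year = min(.data$year), .groups = "drop")
  firsts |>
    rename(severity_level = "level") |>
    inner_join(person_years, by = c("person_id", "year")) |>
    arrange(.data$person_id, .data$severity_level)
}

#' Analysis subsample 2: highest severity level per person-year
#'
#' One row per (person, year) in the study population, keeping only the
#' maximum severity level recorded in that year.  Captures
#' intra-individual variation in AUD severity over time and is the basis
#' for the GEE regression of comorbidity on severity.
#'
#' @inheritParams build_subsample1
#' @return Tibble with `person_id`, `year`, `max_severity_level` and the
#'   person-year covariates.
#' @export
build_subsample2 <- function(person_years, classified) {
  eligible <- inner_join(classified,
                         select(person_years, "person_id", "year"),
                         by = c("person_id", "year"))
  eligible |>
    group_by(.data$person_id, .data$year) |>
    summarise(max_severity_level = max(.data$level), .groups = "drop") |>
    inner_join(person_years, by = c("person_id", "year")) |>
    arrange(.data$person_id, .data$year)
}
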