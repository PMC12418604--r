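#' Elixhauser category flags per person-year
#'
#' Flags each of the 31 Elixhauser comorbidity categories for a
#' person-year when at least one qualifying same-year diagnosis maps to
#' the category under the Quan ICD-10 prefix matching.  Codes not mapping
#' to any category are ignored.  The input must already have passed the
#' qualifier filter ([filter_diagnoses()]): the same record selection is
#' applied to comorbidity as to the AUD diagnoses themselves.
#'
#' @param diagnoses Qualifying diagnoses with `person_id`, `year`,
#'   `icd_code`.
#' @param map Elixhauser category map, see [elixhauser_map()].
#' @return Long tibble `person_id`, `year`, `category`,
#'   `alcohol_specific`; one row per flagged category.
#' @export
ecs_flags <- function(diagnoses, map = elixhauser_map()) {
  hits <- match_elixhauser(unique(diagnoses$icd_code), map)
  alc <- distinct(map, .data$category, .data$alcohol_specific)
  diagnoses |>
    mutate(icd_code = normalize_icd(.data$icd_code)) |>
    select("person_id", "year", "icd_code") |>
    inner_join(hits, by = "icd_code", relationship = "many-to-many") |>
    distinct(.data$person_id, .data$year, .data$category) |>
    left_join(alc, by = "category") |>
    arrange(.data$person_id, .data$year, .data$category)
}

#' Elixhauser comorbidity score (ECS) per person-year
#'
#' The unweighted count of distinct Elixhauser categories flagged in the
#' same calendar year: `ecs_total` in 0-31 (including the alcohol abuse
#' category) and `ecs_nonalcohol` in 0-30 (the 30 categories not specific
#' to alcohol).  Person-years present in the input but mapping to no
#' category receive a score of 0.
#'
#' @inheritParams ecs_flags
#' @return Tibble `person_id`, `year`, `ecs_total`, `ecs_nonalcohol`.
#' @export
#' @examples
#' d <- tibble::tibble(person_id = "P1", year = 2020,
#'                     icd_code = c("F10.2", "I10", "F32.9"))
#' ecs_score(d) # ecs_total 3, ecs_nonalcohol 2
ecs_score <- function(diagnoses, map = elixhauser_map()) {
  flags <- ecs_flags(diagnoses, map)
  base <- distinct(diagnoses, .data$person_id, .data$year)
  scores <- flags |>
    group_by(.data$person_id, .data$year) |>
    summarise(ecs_total = n(),
              ecs_nonalcohol = sum(!.data$alcohol_specific),
              .groups = "drop")
  base |>
    left_join(scores, by = c("person_id", "year")) |>
    mutate(ecs_total = if_else(is.na(.data$ecs_total), 0L,
                               as.integer(.data$ecs_total)),
           ecs_nonalcohol = if_else(is.na(.data$ecs_nonalcohol), 0L,
                                    as.integer(.data$ecs_nonalcohol))) |>
    arrange(.data$person_id, .data$year)
}

#' Share of person-years without non-alcohol comorbidity
#'
#' Among subsample-2 person-years at a given maximum severity level, the
#' proportion with no diagnosis in any of the 30 Elixhauser categories
#' not specific to alcohol (`ecs_nonalcohol == 0`).
#'
#' @param subsample2 Subsample-2 table joined with ECS (columns
#'   `max_severity_level`, `ecs_nonalcohol`).
#' @param level Severity level 1-5.
#' @return A single proportion; `NA` with a warning for an empty stratum.
#' @export
no_comorbidity_share <- function(subsample2, level) {
  rows <- filter(subsample2, .data$max_severity_level == level)
  if (nrow(rows) == 0) {
    warn(sprintf("no person-years at severity level %s; share undefined",
                 level))
    return(NA_real_)
  }
  mean(rows$ecs_nonalcohol == 0)
}
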