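#' Insured persons per year (prevalence denominators)
#'
#' @param coverage Coverage spells.
#' @param years Study years.
#' @return Tibble `year`, `n_insured` (persons with >= 1 insured day).
#' @export
insured_counts <- function(coverage, years) {
  insured_days_by_year(coverage, years) |>
    count(.data$year, name = "n_insured")
}

#' Annual administrative prevalence by severity level
#'
#' For each study year and severity level (0 = any AUD, 1-5), the number
#' of persons classified at that level divided by the number of insured
#' persons, with Wilson score 95% confidence intervals.  Optionally
#' stratified by sex and/or age group (strata denominators are computed
#' from the insured population).
#'
#' @param classified Long severity table from [classify_severity()]
#'   (period `"year"`), already coverage-gated if desired.
#' @param coverage Coverage spells for the full insured population.
#' @param persons Person table (required when `strata` is non-empty, for
#'   sex and birth year).
#' @param years Study years.
#' @param strata Character subset of `c("sex", "age_group")`.
#' @param conf Confidence level.
#' @return Tibble `year`, `level`, strata columns, `n_cases`,
#'   `n_insured`, `prevalence`, `ci_low`, `ci_high`; complete over all
#'   year x level (x stratum) combinations.
#' @export
annual_prevalence <- function(classified, coverage, persons = NULL,
                              years = NULL, strata = character(0),
                              conf = 0.95) {
  if (is.null(years)) years <- sort(unique(classified$year))
  years <- as.integer(years)
  bad <- setdiff(strata, c("sex", "age_group"))
  if (length(bad)) {
    abort(paste0("unknown strata: ", paste(bad, collapse = ", ")))
  }
  if (length(strata) && is.null(persons)) {
    abort("annual_prevalence(): `persons` is required for stratified estimates")
  }

  ins <- insured_days_by_year(coverage, years)
  if (nrow(ins) == 0 || any(!years %in% ins$year)) {
    abort("annual_prevalence(): zero insured persons in at least one requested year; prevalence undefined")
  }
  if (length(strata)) {
    ins <- ins |>
      inner_join(persons, by = "person_id") |>
      mutate(age_group = age_group(age_in_year(.data$birth_year, .data$year)))
  }
  denom <- ins |>
    group_by(across(dplyr::all_of(c("year", strata)))) |>
    summarise(n_insured = n(), .groups = "drop")

  lvl0 <- classified |>
    distinct(.data$person_id, .data$year) |>
    mutate(level = 0L)
  cls <- bind_rows(classified, lvl0) |>
    inner_join(select(ins, dplyr::any_of(c("person_id", "year", "sex",
                                           "age_group"))),
               by = c("person_id", "year"))
  num <- cls |>
    group_by(across(dplyr::all_of(c("year", "level", strata)))) |>
    summarise(n_cases = dplyr::n_distinct(.data$person_id), .groups = "drop")

  grid <- tidyr::expand_grid(
    denom, level = 0:5
  )
  out <- grid |>
    left_join(num, by = c("year", "level", strata)) |>
    mutate(n_cases = if_else(is.na(.data$n_cases), 0L,
                             as.integer(.data$n_cases)))
  ci <- wilson_ci(out$n_cases, out$n_insured, conf)
  out |>
    mutate(prevalence = ci$estimate, ci_low = ci$ci_low,
           ci_high = ci$ci_high) |>
    select(dplyr::all_of(c("year", "level", strata, "n_cases", "n_insured",
                           "prevalence", "ci_low", "ci_high"))) |>
    arrange(across(dplyr::all_of(c("level", "year", strata))))
}

#' Average prevalence across study years
#'
#' The unweighted mean of the annual prevalence proportions per severity
#' level.  Requires an estimate for every study year.
#'
#' @param prevalence Output of [annual_prevalence()] (unstratified).
#' @param years The study years that must all be present.
#' @return Tibble `level`, `avg_prevalence`.
#' @export
average_prevalence <- function(prevalence, years = NULL) {
  if (is.null(years)) years <- sort(unique(prevalence$year))
  missing <- prevalence |>
    group_by(.data$level) |>
    summarise(ok = all(years %in% .data$year), .groups = "drop")
  if (any(!missing$ok)) {
    abort("average_prevalence(): missing annual estimates for some level(s)")
  }
  prevalence |>
    filter(.data$year %in% years) |>
    group_by(.data$level) |>
    summarise(avg_prevalence = mean(.data$prevalence), .groups = "drop")
}

#' Overlap of severity levels across the study window
#'
#' Summarises how persons' study-window severity-level sets overlap:
#' counts for each of the 31 non-empty level combinations (Venn regions),
#' pairwise intersection counts, and per level the share of its members
#' that also carry at least one diagnosis from another severity level.
#'
#' @param classified_window Long severity table from
#'   [classify_severity()] with `period = "window"`.
#' @return A list of tibbles: `regions` (`levels`, `n`), `pairwise`
#'   (`level_a`, `level_b`, `n`), and `share_with_other` (`level`, `n`,
#'   `n_with_other`, `share`).
#' @export
overlap_summary <- function(classified_window) {
  sets <- classified_window |>
    group_by(.data$person_id) |>
    summarise(key = paste(sort(unique(.data$level)), collapse = "+"),
              n_levels = dplyr::n_distinct(.data$level), .groups = "drop")

  all_keys <- unlist(lapply(1:5, function(k) {
    utils::combn(1:5, k, FUN = paste, collapse = "+")
  }))
  regions <- sets |>
    count(.data$key, name = "n") |>
    dplyr::right_join(tibble(key = all_keys), by = "key") |>
    mutate(n = if_else(is.na(.data$n), 0L, as.integer(.data$n))) |>
    rename(levels = "key") |>
    arrange(.data$levels)

  pairs <- utils::combn(1:5, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    members <- classified_window |>
      group_by(.data$person_id) |>
      summarise(both = all(c(a, b) %in% .data$level), .groups = "drop")
    tibble(level_a = a, level_b = b, n = sum(members$both))
  })

  share <- purrr::map_dfr(1:5, function(l) {
    members <- sets$key[vapply(strsplit(sets$key, "\\+"),
                               function(s) as.character(l) %in% s,
                               logical(1))]
    n <- length(members)
    n_other <- sum(members != as.character(l))
    tibble(level = l, n = n, n_with_other = n_other,
           share = if (n > 0) n_other / n else NA_real_)
  })

  list(regions = regions, pairwise = pairwise, share_with_other = share)
}

#' GEE Poisson regression of comorbidity on AUD severity
#'
#' Fits the population-averaged dose-response model of the Elixhauser
#' comorbidity score on the maximum annual AUD severity level (reference:
#' level 1), adjusted for year, sex, age group and employment status,
#' with an exchangeable working correlation across a person's repeated
#' annual observations and robust standard errors.
#'
#' @param subsample2 Subsample-2 table joined with ECS: columns
#'   `person_id`, `year`, `max_severity_level`, `ecs`, plus the
#'   adjustment covariates.
#' @param corstr Working correlation structure (see [gee_poisson()]).
#' @param covariates Adjustment covariates to include (subset of
#'   `c("year", "sex", "age_group", "employment")`).
#' @return An `aud_gee` fit whose severity terms are named
#'   `severity2`..`severity5`.
#' @export
fit_severity_gee <- function(subsample2,
                             corstr = c("exchangeable", "independence",
                                        "unstructured"),
                             covariates = c("year", "sex", "age_group",
                                            "employment")) {
  corstr <- match.arg(corstr)
  d <- subsample2
  lv <- sort(unique(d$max_severity_level))
  if (length(lv) < 2) {
    abort("fit_severity_gee(): need at least two severity levels present")
  }
  d$severity <- factor(d$max_severity_level, levels = sort(union(1:5, lv)))
  d$severity <- stats::relevel(d$severity, ref = "1")
  d$severity <- droplevels(d$severity)
  if ("year" %in% covariates) d$year_f <- factor(d$year)
  if ("employment" %in% covariates) {
    d$employment <- factor(d$employment, levels = employment_levels())
  }
  rhs <- c("severity",
           if ("year" %in% covariates && length(unique(d$year)) > 1) "year_f",
           if ("sex" %in% covariates) "sex",
           if ("age_group" %in% covariates) "age_group",
           if ("employment" %in% covariates) "employment")
  # drop covariates without variation (degenerate strata)
  rhs <- rhs[vapply(rhs, function(v) length(unique(d[[v]])) > 1, logical(1))]
  f <- stats::reformulate(rhs, response = "ecs")
  gee_poisson(f, d, id = person_id, corstr = corstr, time = year)
}
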