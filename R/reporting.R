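iqr_bounds <- function(x) {
  # linear-interpolation quantiles (R type 7), the documented IQR rule
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  list(q25 = q[1], q75 = q[2])
}

#' Descriptive summary of the study population by severity level
#'
#' One row per severity level (0 = any AUD, 1-5) computed on subsample 1,
#' i.e. on each person's first year at that level: group size, share of
#' women, age mean and interquartile range, employment distribution, and
#' ECS mean and interquartile range.  Levels without members yield a row
#' of explicit `NA`s.
#'
#' @param subsample1 Subsample-1 table from [build_subsample1()] joined
#'   with an `ecs` column.
#' @return A tibble with one row per severity level.
#' @export
table2_summary <- function(subsample1) {
  stopifnot("ecs" %in% names(subsample1))
  filled <- purrr::map_dfr(0:5, function(l) {
    rows <- filter(subsample1, .data$severity_level == l)
    if (nrow(rows) == 0) {
      return(tibble(severity_level = l, n = 0L, pct_female = NA_real_,
                    age_mean = NA_real_, age_q25 = NA_real_,
                    age_q75 = NA_real_, pct_employed = NA_real_,
                    pct_unemployed = NA_real_, pct_retired = NA_real_,
                    pct_other = NA_real_, ecs_mean = NA_real_,
                    ecs_q25 = NA_real_, ecs_q75 = NA_real_))
    }
    aq <- iqr_bounds(rows$age)
    eq <- iqr_bounds(rows$ecs)
    emp <- table(factor(rows$employment, levels = employment_levels()))
    emp <- as.numeric(emp) / nrow(rows)
    tibble(
      severity_level = l,
      n = nrow(rows),
      pct_female = mean(rows$sex == "female"),
      age_mean = mean(rows$age), age_q25 = aq$q25, age_q75 = aq$q75,
      pct_employed = emp[1], pct_unemployed = emp[2],
      pct_retired = emp[3], pct_other = emp[4],
      ecs_mean = mean(rows$ecs), ecs_q25 = eq$q25, ecs_q75 = eq$q75
    )
  })
  filled
}

#' Share of person-years flagged for each Elixhauser category, by severity
#'
#' For each maximum severity level in subsample 2 and each of the 31
#' Elixhauser categories, the share of person-years carrying the flag in
#' the same year as the severity classification.
#'
#' @param subsample2 Subsample-2 table (`person_id`, `year`,
#'   `max_severity_level`).
#' @param flags Long category flags from [ecs_flags()].
#' @return Tibble `max_severity_level`, `category`, `n`, `share`;
#'   complete over level x category.
#' @export
comorbidity_share_table <- function(subsample2, flags) {
  cats <- unique(elixhauser_map()$category)
  denom <- count(subsample2, .data$max_severity_level, name = "n_total")
  joined <- subsample2 |>
    select("person_id", "year", "max_severity_level") |>
    inner_join(flags, by = c("person_id", "year"))
  num <- count(joined, .data$max_severity_level, .data$category, name = "n")
  tidyr::expand_grid(
    max_severity_level = sort(unique(subsample2$max_severity_level)),
    category = cats
  ) |>
    left_join(num, by = c("max_severity_level", "category")) |>
    mutate(n = if_else(is.na(.data$n), 0L, as.integer(.data$n))) |>
    inner_join(denom, by = "max_severity_level") |>
    mutate(share = .data$n / .data$n_total) |>
    select(-"n_total")
}

#' Run the full synthetic-claims analysis pipeline
#'
#' Simulates a claims dataset, applies the qualifier filter, dates and
#' classifies the diagnoses, builds the study population and both
#' analysis subsamples, scores comorbidity, estimates annual and average
#' prevalence, summarises severity-level overlap, fits the severity GEE
#' (when feasible) and produces the descriptive tables.  Every artifact
#' is regenerable from the raw synthetic tables alone; a manifest records
#' seed, config hash, per-stage row counts and dropped-record counts.
#'
#' @param config An [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @param gee `TRUE` to fit the severity GEE (skipped automatically when
#'   fewer than two severity levels are present).
#' @return An `aud_pipeline` list with all stage outputs and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), seed = NULL, gee = TRUE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  inform("simulating claims data")
  sim <- simulate_claims(config)

  inform("filtering and dating diagnoses")
  kept <- filter_diagnoses(sim$diagnoses)
  dated <- assign_dates(kept)

  inform("classifying severity")
  classified <- classify_severity(dated, period = "year")
  classified_window <- classify_severity(dated, period = "window")

  inform("building person-years and subsamples")
  person_years <- build_person_years(
    sim$persons, sim$coverage_spells, classified, config$years,
    employment_spells = sim$employment_spells
  )
  ss1 <- build_subsample1(person_years, classified)
  ss2 <- build_subsample2(person_years, classified)

  inform("scoring comorbidity")
  ecs <- ecs_score(dated)
  flags <- ecs_flags(dated)
  join_ecs <- function(tab) {
    tab |>
      left_join(ecs, by = c("person_id", "year")) |>
      mutate(ecs = if_else(is.na(.data$ecs_total), 0L, .data$ecs_total))
  }
  ss1 <- join_ecs(ss1)
  ss2 <- join_ecs(ss2)

  inform("estimating prevalence and overlap")
  prevalence <- annual_prevalence(classified, sim$coverage_spells,
                                  years = config$years)
  avg_prev <- average_prevalence(prevalence, config$years)
  overlap <- overlap_summary(classified_window)

  fit <- NULL
  if (gee && length(unique(ss2$max_severity_level)) >= 2 && nrow(ss2) > 0) {
    inform("fitting severity GEE")
    if (length(unique(ss2$year)) == 1) {
      warn("single study year: GEE reduces to independence working correlation")
    }
    fit <- fit_severity_gee(ss2)
  }

  tab2 <- table2_summary(ss1)
  com_shares <- comorbidity_share_table(ss2, flags)

  drop_log <- attr(kept, "drop_log")
  manifest <- list(
    seed = config$seed,
    config_hash = hash(unclass(config)),
    n_rows = c(
      persons = nrow(sim$persons),
      diagnoses_raw = nrow(sim$diagnoses),
      diagnoses_kept = nrow(kept),
      classified_person_years = nrow(distinct(classified, .data$person_id,
                                              .data$year)),
      study_persons = dplyr::n_distinct(person_years$person_id),
      subsample1 = nrow(ss1),
      subsample2 = nrow(ss2)
    ),
    dropped = setNames(drop_log$n, drop_log$reason),
    dropped_no_coverage = attr(person_years, "dropped_no_coverage")
  )

  structure(list(
    sim = sim, diagnoses_kept = kept, dated = dated,
    classified = classified, classified_window = classified_window,
    person_years = person_years, subsample1 = ss1, subsample2 = ss2,
    ecs = ecs, flags = flags, prevalence = prevalence,
    average_prevalence = avg_prev, overlap = overlap, gee = fit,
    table2 = tab2, comorbidity_shares = com_shares, manifest = manifest
  ), class = "aud_pipeline")
}

#' @export
print.aud_pipeline <- function(x, ...) {
  cat("<aud_pipeline> synthetic claims analysis bundle\n")
  cat(sprintf("  seed %d, config hash %s\n", x$manifest$seed,
              x$manifest$config_hash))
  cat("  row counts:\n")
  for (nm in names(x$manifest$n_rows)) {
    cat(sprintf("    %-24s %d\n", nm, x$manifest$n_rows[[nm]]))
  }
  invisible(x)
}

#' Plot annual administrative prevalence by severity level
#'
#' @param prevalence Output of [annual_prevalence()].
#' @return A ggplot object with error bars for the Wilson 95% CIs.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$year, y = .data$prevalence,
                               colour = factor(.data$level))) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2, position = ggplot2::position_dodge(0.4)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.1f%%",
                                                             100 * v)) +
    ggplot2::labs(x = NULL, y = "Administrative prevalence",
                  colour = "Severity level") +
    ggplot2::theme_minimal()
}

#' Plot Elixhauser category shares by severity level
#'
#' @param shares Output of [comorbidity_share_table()].
#' @param top_n Show only the `top_n` most frequent categories.
#' @return A ggplot object.
#' @export
plot_comorbidity_shares <- function(shares, top_n = 12) {
  keep <- shares |>
    group_by(.data$category) |>
    summarise(s = max(.data$share), .groups = "drop") |>
    slice_max(.data$s, n = top_n) |>
    pull(.data$category)
  ggplot2::ggplot(
    filter(shares, .data$category %in% keep),
    ggplot2::aes(x = .data$share, y = stats::reorder(.data$category,
                                                     .data$share),
                 fill = factor(.data$max_severity_level))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "Share of person-years", y = NULL,
                  fill = "Max severity") +
    ggplot2::theme_minimal()
}
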