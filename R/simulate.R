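#' Simulate a complete synthetic claims dataset
#'
#' Convenience wrapper running [simulate_cohort()] and
#' [simulate_diagnoses()] under one configuration.  The result carries the
#' planted ground truth, so downstream estimates can be checked against
#' the generating parameters (parameter recovery).
#'
#' @param config An [sim_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return An object of class `aud_sim`: a list with tibbles `persons`,
#'   `coverage_spells`, `employment_spells`, `diagnoses`, the planted
#'   `truth`, and the `config` used.
#' @export
#' @examples
#' sim <- simulate_claims(sim_config(n_persons = 200, insured_pool_size = 1000,
#'                                   frailty_var = 0.5, seed = 42))
#' sim$diagnoses
simulate_claims <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- simulate_cohort(config)
  diag <- simulate_diagnoses(cohort, config)
  structure(
    c(cohort, diag, list(config = config)),
    class = "aud_sim"
  )
}

#' @export
print.aud_sim <- function(x, ...) {
  cat("<aud_sim> synthetic claims dataset\n")
  cat(sprintf("  persons: %d (at risk: %d), years %s-%s\n",
              nrow(x$persons), sum(x$persons$at_risk),
              min(x$config$years), max(x$config$years)))
  cat(sprintf("  diagnosis records: %d\n", nrow(x$diagnoses)))
  cat(sprintf("  planted person-year level assignments: %d\n",
              nrow(x$truth$person_year_levels)))
  invisible(x)
}

#' Planted ground truth of a simulation
#'
#' Returns exactly the values the generator used: the per-person-year
#' severity-level sets, per-level prevalences, log rate ratios of ECS,
#' planted per-level ECS means, the within-person correlation target and
#' the frailty variance that was used to induce it.
#'
#' @param x An `aud_sim` object (full per-person truth) or an
#'   [sim_config()] (parameter-level truth only).
#' @return A list of ground-truth components.
#' @export
planted_truth <- function(x) {
  if (inherits(x, "aud_sim")) return(x$truth)
  if (inherits(x, "aud_sim_config")) {
    return(list(params = list(
      prevalence_level0 = x$prevalence_level0,
      prevalence_by_level = x$prevalence_by_level,
      severity_log_rr = x$severity_log_rr,
      ecs_mean_by_level = setNames(
        x$baseline_ecs_mean * exp(c(0, x$severity_log_rr)),
        as.character(1:5)),
      target_within_person_corr = x$target_within_person_corr,
      frailty_var = x$frailty_var
    )))
  }
  abort("planted_truth() expects an `aud_sim` or `aud_sim_config` object")
}

#' Write the simulated tables to CSV files
#'
#' Writes persons, coverage spells, employment spells, diagnoses and the
#' planted person-year truth as plain CSV files with fixed column schemas.
#'
#' @param sim An `aud_sim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_sim_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "aud_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(
    persons = sim$persons,
    coverage_spells = sim$coverage_spells,
    employment_spells = sim$employment_spells,
    diagnoses = sim$diagnoses,
    truth_person_year_levels = sim$truth$person_year_levels
  )
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tabs[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
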