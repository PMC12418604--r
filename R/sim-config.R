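#' Configuration for the synthetic claims generator
#'
#' Defines the stated world the generator emulates: an insured population
#' observed over several calendar years, a pool of persons at risk of
#' alcohol-specific diagnoses, planted annual prevalences per AUD severity
#' level, planted multiplicative severity effects on the Elixhauser
#' comorbidity score (ECS), and a person-level frailty that induces the
#' targeted within-person correlation of ECS across years.
#'
#' Defaults are calibrated to the published claims analysis this pipeline
#' emulates: any-AUD annual prevalence 2.7% (pre-2020 years) and 2.9%
#' (2020 onwards), level-specific prevalences 0.4/1.3/1.5/0.2/0.7% for
#' levels 1-5, ECS rate ratios 1.24/1.32/1.47/1.65 for levels 2-5 versus
#' level 1, a level-1 mean ECS of 3.5, and a within-person ECS correlation
#' of 0.708.
#'
#' @param n_persons Size of the at-risk pool from which AUD cases arise.
#'   Each at-risk person is independently "active" (carries at least one
#'   alcohol-specific diagnosis) in each year with probability
#'   `prevalence_level0[year] * insured_pool_size / n_persons`, so the
#'   expected annual number of any-AUD cases equals the planted prevalence
#'   times the insured denominator.
#' @param insured_pool_size Number of insured persons per year (the
#'   prevalence denominator).  Every simulated person is insured at least
#'   one day in every study year.
#' @param years Calendar years of the study window.
#' @param prevalence_level0 Named numeric, annual any-AUD prevalence per
#'   year.  Default: 0.027 before 2020, 0.029 from 2020.
#' @param prevalence_by_level Named numeric (names "1".."5"), annual
#'   prevalence of each severity level.  Each must not exceed the smallest
#'   any-AUD prevalence.
#' @param severity_log_rr Named numeric (names "2".."5"), planted log rate
#'   ratios of ECS for maximum severity levels 2-5 versus level 1.
#' @param baseline_ecs_mean Planted population-average ECS at severity
#'   level 1.
#' @param target_within_person_corr Target exchangeable correlation of ECS
#'   across years within persons; the gamma frailty variance is solved
#'   numerically to induce it (see `frailty_var`).
#' @param frailty_var Person-level frailty variance.  `NULL` (default)
#'   solves it from `target_within_person_corr` by pilot simulation; `0`
#'   disables the frailty entirely.
#' @param covar_log_rr Planted log rate ratios for the adjustment
#'   covariates, a list with elements `sex_female` (scalar), `age_group`
#'   (length 7), `employment` (length 4) and `year` (one per study year).
#'   All zero by default; when non-zero, the intercept is re-centred so
#'   the population-average ECS per severity level is unchanged.
#' @param sex_female_prop Proportion female among at-risk persons.
#' @param age_mean,age_sd Normal age distribution (at the first study
#'   year) for at-risk persons, truncated to 18-95.
#' @param employment_dist Named proportions over
#'   employed/unemployed/retired/other.
#' @param employment_sticky Probability that a person keeps the previous
#'   year's employment status.
#' @param employment_split_frac Fraction of person-years whose employment
#'   is split into two spells (a minority secondary status), exercising
#'   the most-days resolution rule.
#' @param overlap_structure `"calibrated"` (default): severity-level sets
#'   are drawn from a joint distribution whose conditional level marginals
#'   match the planted prevalences, so levels overlap within person-years;
#'   `"none"`: every active person-year carries exactly one level (drawn
#'   proportionally to the planted prevalences), a degenerate mode for
#'   testing.
#' @param level4_implies_level3 Probability that a planted level-4
#'   (withdrawal) year also carries a level-3 (dependence) diagnosis;
#'   withdrawal is clinically nested in dependence, and this knob controls
#'   the planted containment.
#' @param level5_signature_dist Distribution of the level-5 diagnostic
#'   signature per person: alcoholic liver disease codes only
#'   (`k70_only`), higher-order F10 codes only (`f10_59_only`), alcoholic
#'   polyneuropathy only (`g62_only`), or a combination of groups.
#' @param outpatient_prop Probability that a record is billed in the
#'   outpatient (quarterly) rather than inpatient (dated) setting.
#' @param noise_outpatient,noise_inpatient Per-record probability of an
#'   additional non-qualifying record (outpatient: exclusionary /
#'   suspecting / symptomless; inpatient: surgery / follow-up), planted to
#'   exercise the qualifier filters; the implied share of non-qualifying
#'   records stays below the 10% (outpatient) and 4% (inpatient) levels
#'   observed in practice.
#' @param excluded_code_rate Per active person-year probability of a
#'   confirmed R78.0 / O35.4 record (codes excluded from classification).
#' @param extra_records_mean Poisson mean of additional qualifying records
#'   per (person, year, level) beyond the guaranteed one.
#' @param partial_coverage_frac Fraction of persons whose coverage spell
#'   starts after Jan 1 of the first year and ends before Dec 31 of the
#'   last year (still covering at least one day of every study year, so
#'   annual denominators are conserved).
#' @param ecs_category_weights Named non-negative weights over Elixhauser
#'   categories governing which extra comorbidity categories are drawn.
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return An object of class `aud_sim_config` (a validated list).
#' @export
sim_config <- function(n_persons = 20000,
                       insured_pool_size = 100000,
                       years = 2017:2021,
                       prevalence_level0 = NULL,
                       prevalence_by_level = c(`1` = 0.004, `2` = 0.013,
                                               `3` = 0.015, `4` = 0.002,
                                               `5` = 0.007),
                       severity_log_rr = log(c(`2` = 1.24, `3` = 1.32,
                                               `4` = 1.47, `5` = 1.65)),
                       baseline_ecs_mean = 3.5,
                       target_within_person_corr = 0.708,
                       frailty_var = NULL,
                       covar_log_rr = NULL,
                       sex_female_prop = 0.306,
                       age_mean = 53.8,
                       age_sd = 16,
                       employment_dist = c(employed = 0.418,
                                           unemployed = 0.251,
                                           retired = 0.177,
                                           other = 0.154),
                       employment_sticky = 0.85,
                       employment_split_frac = 0.1,
                       overlap_structure = c("calibrated", "none"),
                       level4_implies_level3 = 0.9,
                       level5_signature_dist = c(k70_only = 0.40,
                                                 f10_59_only = 0.21,
                                                 g62_only = 0.096,
                                                 combination = 0.294),
                       outpatient_prop = 0.7,
                       noise_outpatient = 0.08,
                       noise_inpatient = 0.03,
                       excluded_code_rate = 0.002,
                       extra_records_mean = 0.6,
                       partial_coverage_frac = 0.1,
                       ecs_category_weights = NULL,
                       seed = 1L) {
  years <- sort(as.integer(years))
  if (is.null(prevalence_level0)) {
    prevalence_level0 <- setNames(ifelse(years >= 2020, 0.029, 0.027),
                                  as.character(years))
  }
  if (is.null(names(prevalence_level0))) {
    names(prevalence_level0) <- as.character(years)
  }
  if (is.null(covar_log_rr)) covar_log_rr <- list()
  covar_log_rr <- utils::modifyList(list(
    sex_female = 0,
    age_group = setNames(numeric(7), levels(age_group(18))),
    employment = setNames(numeric(4), employment_levels()),
    year = setNames(numeric(length(years)), as.character(years))
  ), covar_log_rr)
  if (is.null(ecs_category_weights)) {
    ecs_category_weights <- default_ecs_weights()
  }

  cfg <- structure(list(
    n_persons = as.integer(n_persons),
    insured_pool_size = as.integer(insured_pool_size),
    years = years,
    prevalence_level0 = prevalence_level0,
    prevalence_by_level = prevalence_by_level,
    severity_log_rr = severity_log_rr,
    baseline_ecs_mean = baseline_ecs_mean,
    target_within_person_corr = target_within_person_corr,
    frailty_var = frailty_var,
    covar_log_rr = covar_log_rr,
    sex_female_prop = sex_female_prop,
    age_mean = age_mean, age_sd = age_sd,
    employment_dist = employment_dist,
    employment_sticky = employment_sticky,
    employment_split_frac = employment_split_frac,
    overlap_structure = match.arg(overlap_structure),
    level4_implies_level3 = level4_implies_level3,
    level5_signature_dist = level5_signature_dist,
    outpatient_prop = outpatient_prop,
    noise_outpatient = noise_outpatient,
    noise_inpatient = noise_inpatient,
    excluded_code_rate = excluded_code_rate,
    extra_records_mean = extra_records_mean,
    partial_coverage_frac = partial_coverage_frac,
    ecs_category_weights = ecs_category_weights,
    seed = as.integer(seed)
  ), class = "aud_sim_config")
  validate_sim_config(cfg)
}

# Relative weights for drawing extra (non-planted) comorbidity categories;
# ordered so the resulting category shares resemble a claims population with
# frequent depression, hypertension and chronic pulmonary disease.
default_ecs_weights <- function() {
  c(depression = 10, hypertension_uncomplicated = 9, chronic_pulmonary = 6,
    fluid_electrolyte = 5, diabetes_uncomplicated = 4,
    cardiac_arrhythmias = 4, liver_disease = 3.5, drug_abuse = 3,
    other_neurological = 3, obesity = 3, psychoses = 2.5,
    hypothyroidism = 2.5, renal_failure = 2, congestive_heart_failure = 2,
    hypertension_complicated = 2, weight_loss = 2, deficiency_anemia = 2,
    alcohol_abuse = 2, peripheral_vascular = 2, valvular_disease = 1.5,
    solid_tumor = 1.5, coagulopathy = 1.5, rheumatoid_arthritis = 1,
    paralysis = 0.8, pulmonary_circulation = 0.8, peptic_ulcer = 0.8,
    diabetes_complicated = 0.8, metastatic_cancer = 0.5,
    blood_loss_anemia = 0.5, lymphoma = 0.4, aids_hiv = 0.2)
}

validate_sim_config <- function(cfg) {
  chk_prop <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      abort_config(field, "all values must be proportions in [0, 1]")
    }
  }
  if (is.na(cfg$n_persons) || cfg$n_persons < 0) {
    abort_config("n_persons", "must be a non-negative integer")
  }
  if (is.na(cfg$insured_pool_size) || cfg$insured_pool_size < 0) {
    abort_config("insured_pool_size", "must be a non-negative integer")
  }
  if (cfg$n_persons > cfg$insured_pool_size) {
    abort_config("n_persons", "cannot exceed `insured_pool_size`")
  }
  if (length(cfg$years) < 1) abort_config("years", "needs at least one year")
  if (!identical(names(cfg$prevalence_level0), as.character(cfg$years))) {
    abort_config("prevalence_level0", "must be named by the study years")
  }
  chk_prop(cfg$prevalence_level0, "prevalence_level0")
  if (!identical(names(cfg$prevalence_by_level), as.character(1:5))) {
    abort_config("prevalence_by_level", 'must be named "1".."5"')
  }
  chk_prop(cfg$prevalence_by_level, "prevalence_by_level")
  if (any(cfg$prevalence_by_level > min(cfg$prevalence_level0))) {
    abort_config("prevalence_by_level",
                 "level-specific prevalences cannot exceed the any-AUD prevalence")
  }
  if (!identical(names(cfg$severity_log_rr), as.character(2:5))) {
    abort_config("severity_log_rr", 'must be named "2".."5"')
  }
  if (cfg$baseline_ecs_mean <= 0) {
    abort_config("baseline_ecs_mean", "must be positive")
  }
  if (cfg$target_within_person_corr <= 0 || cfg$target_within_person_corr >= 1) {
    abort_config("target_within_person_corr", "must lie in (0, 1)")
  }
  if (!is.null(cfg$frailty_var) && cfg$frailty_var < 0) {
    abort_config("frailty_var", "must be non-negative (or NULL to calibrate)")
  }
  chk_prop(cfg$sex_female_prop, "sex_female_prop")
  if (abs(sum(cfg$employment_dist) - 1) > 1e-8 ||
      !identical(names(cfg$employment_dist), employment_levels())) {
    abort_config("employment_dist",
                 "must be proportions over employed/unemployed/retired/other summing to 1")
  }
  chk_prop(cfg$level4_implies_level3, "level4_implies_level3")
  if (abs(sum(cfg$level5_signature_dist) - 1) > 1e-6) {
    abort_config("level5_signature_dist", "must sum to 1")
  }
  chk_prop(cfg$outpatient_prop, "outpatient_prop")
  chk_prop(cfg$noise_outpatient, "noise_outpatient")
  chk_prop(cfg$noise_inpatient, "noise_inpatient")
  chk_prop(cfg$partial_coverage_frac, "partial_coverage_frac")
  if (any(cfg$ecs_category_weights < 0)) {
    abort_config("ecs_category_weights", "weights must be non-negative")
  }
  # annual activity probability among the at-risk pool must be a probability
  if (cfg$n_persons > 0) {
    p_act <- max(cfg$prevalence_level0) * cfg$insured_pool_size / cfg$n_persons
    if (p_act > 1) {
      abort_config("n_persons", sprintf(
        "too small: implied annual activity probability %.2f exceeds 1; increase n_persons or lower prevalence_level0",
        p_act))
    }
  }
  cfg
}

#' @export
print.aud_sim_config <- function(x, ...) {
  cat("<aud_sim_config>\n")
  cat(sprintf("  at-risk persons: %d, insured pool per year: %d\n",
              x$n_persons, x$insured_pool_size))
  cat(sprintf("  years: %s\n", paste(x$years, collapse = ", ")))
  cat(sprintf("  any-AUD prevalence: %s\n",
              paste(sprintf("%s=%.3f", names(x$prevalence_level0),
                            x$prevalence_level0), collapse = " ")))
  cat(sprintf("  level prevalences: %s\n",
              paste(sprintf("%s=%.3f", names(x$prevalence_by_level),
                            x$prevalence_by_level), collapse = " ")))
  cat(sprintf("  ECS rate ratios (vs level 1): %s\n",
              paste(sprintf("%s=%.2f", names(x$severity_log_rr),
                            exp(x$severity_log_rr)), collapse = " ")))
  cat(sprintf("  baseline ECS mean: %.2f, target within-person corr: %.3f\n",
              x$baseline_ecs_mean, x$target_within_person_corr))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
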