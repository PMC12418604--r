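#' Wilson score confidence interval for a binomial proportion
#'
#' Used for administrative prevalence estimates; behaves sensibly at
#' numerator 0 and at numerator = denominator (interval endpoints are
#' pinned to 0 and 1 respectively).
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials (vectorised, must be positive).
#' @param conf Confidence level, default 0.95.
#' @return A tibble with columns `estimate`, `ci_low`, `ci_high`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (any(n <= 0)) {
    abort("wilson_ci(): denominator `n` must be positive.")
  }
  if (any(x < 0 | x > n)) {
    abort("wilson_ci(): `x` must lie in [0, n].")
  }
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(
    estimate = p,
    ci_low = pmin(pmax(0, centre - half), p),
    ci_high = pmax(pmin(1, centre + half), p)
  )
}

# Derive a deterministic substream seed (< 2^31) from a top-level seed and a
# stream label, so each simulation stage has its own reproducible stream.
derive_seed <- function(seed, stream) {
  offsets <- c(cohort = 11L, diagnoses = 23L, calibration = 37L, pipeline = 53L)
  off <- offsets[[stream]] %||% abort(paste0("unknown RNG stream: ", stream))
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Age attained in the calendar year (calendar-year convention).
age_in_year <- function(birth_year, year) as.integer(year - birth_year)

#' Age groups used for stratified prevalence and regression adjustment
#'
#' Seven groups: 18-24, 25-34, 35-44, 45-54, 55-64, 65-74, 75+.
#'
#' @param age Integer vector of ages in years.
#' @return A factor with seven levels.
#' @export
age_group <- function(age) {
  cut(age,
    breaks = c(18, 25, 35, 45, 55, 65, 75, Inf),
    labels = c("18-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+"),
    right = FALSE, include.lowest = TRUE
  )
}

# Hierarchy used to break ties when resolving annual employment status.
employment_levels <- function() c("employed", "unemployed", "retired", "other")

# normalise ICD codes: trim, uppercase; the dot is retained
normalize_icd <- function(x) toupper(trimws(x))

abort_config <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "audsev_config_error")
}
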