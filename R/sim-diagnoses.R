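# ---- planted severity level sets ------------------------------------------

# Joint distribution over the 31 non-empty severity-level subsets for one
# active person-year.  Draw probabilities d are solved by fixed point so
# that, after the withdrawal->dependence containment boost and conditioning
# on a non-empty set, the marginal probability of each level equals the
# target conditional prevalence c_l = P(level l | any AUD).
solve_level_patterns <- function(cond_prev, boost) {
  stopifnot(length(cond_prev) == 5, all(cond_prev > 0), all(cond_prev < 1))
  bits <- as.matrix(expand.grid(rep(list(0:1), 5)))[, 5:1]
  colnames(bits) <- paste0("l", 1:5)

  pattern_probs <- function(d) {
    p <- exp(bits %*% log(d) + (1 - bits) %*% log(1 - d))[, 1]
    # containment boost: a set with level 4 but not level 3 gains level 3
    from <- which(bits[, 4] == 1 & bits[, 3] == 0)
    to <- vapply(from, function(i) {
      tgt <- bits[i, ]; tgt[3] <- 1
      which(apply(bits, 1, function(b) all(b == tgt)))
    }, integer(1))
    moved <- p[from] * boost
    p[from] <- p[from] - moved
    p[to] <- p[to] + moved
    nonempty <- rowSums(bits) > 0
    p <- p[nonempty] / sum(p[nonempty])
    list(bits = bits[nonempty, , drop = FALSE], probs = p)
  }

  d <- pmin(cond_prev, 0.95)
  for (it in 1:500) {
    pp <- pattern_probs(d)
    m <- colSums(pp$bits * pp$probs)
    if (max(abs(m - cond_prev)) < 1e-10) break
    d <- pmin(0.999, pmax(1e-8, d * cond_prev / m))
  }
  if (max(abs(m - cond_prev)) > 1e-6) {
    abort("could not calibrate severity-level pattern probabilities; the requested level prevalences are jointly infeasible")
  }
  pp
}

# pattern distribution used by the generator for a given year: calibrated
# overlapping sets, or degenerate single-level sets (overlap disabled)
level_pattern_dist <- function(config, year_chr) {
  cond <- config$prevalence_by_level / config$prevalence_level0[year_chr]
  if (config$overlap_structure == "none") {
    bits <- diag(5)
    colnames(bits) <- paste0("l", 1:5)
    return(list(bits = bits, probs = unname(cond / sum(cond))))
  }
  solve_level_patterns(cond, config$level4_implies_level3)
}

# ---- comorbidity planting ---------------------------------------------------

# Bernoulli category probabilities with total mass `target` spread over the
# eligible categories proportionally to `weights`, with per-category caps at
# 1 resolved by water-filling (vectorised bisection over rows).
waterfill_probs <- function(target, eligible, weights) {
  n <- length(target)
  W <- matrix(rep(weights, each = n), n) * eligible
  cap <- rowSums(eligible) - 1e-9
  target <- pmin(pmax(target, 0), cap)
  lo <- rep(0, n)
  hi <- rep((max(target) + 31) / max(min(weights[weights > 0]), 1e-6), n)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f <- rowSums(pmin(mid * W, 1)) - target
    over <- f > 0
    hi[over] <- mid[over]
    lo[!over] <- mid[!over]
  }
  pmin(((lo + hi) / 2) * W, 1)
}

# Expected-multiplier centring of the covariate effects, so that planted
# severity-level ECS means are population-average quantities regardless of
# the covariate effect sizes.
covar_centring <- function(config) {
  eff <- config$covar_log_rr
  if (all(unlist(eff) == 0)) {
    return(list(cbar = 0, min_log = 0, active = FALSE))
  }
  pf <- config$sex_female_prop
  e_sex <- pf * exp(eff$sex_female) + (1 - pf)
  mid_year <- config$years[ceiling(length(config$years) / 2)]
  mean_age <- config$age_mean + (mid_year - config$years[1])
  brk <- c(18, 25, 35, 45, 55, 65, 75, Inf)
  pr_age <- diff(pnorm(brk, mean_age, config$age_sd))
  pr_age <- pr_age / sum(pr_age)
  e_age <- sum(pr_age * exp(eff$age_group))
  e_emp <- sum(config$employment_dist * exp(eff$employment))
  e_year <- mean(exp(eff$year))
  cbar <- log(e_sex) + log(e_age) + log(e_emp) + log(e_year)
  min_log <- min(0, eff$sex_female) + min(eff$age_group) +
    min(eff$employment) + min(eff$year)
  list(cbar = cbar, min_log = min_log, active = TRUE)
}

# Lower support bound for the frailty so that the planted conditional mean
# always covers the comorbidity count intrinsic to the severity codes
# themselves (1 category for levels 1-4, typically 2 for level 5).
frailty_shift <- function(config, centring) {
  rr <- exp(c(`1` = 0, config$severity_log_rr))
  k_lvl <- c(1, 1, 1, 1, 2)
  min_mult <- exp(centring$min_log - centring$cbar)
  a <- max(k_lvl / (config$baseline_ecs_mean * rr * min_mult))
  if (a >= 0.95) {
    abort_config("baseline_ecs_mean",
                 "too small relative to the intrinsic comorbidity of the severity codes; frailty support is infeasible")
  }
  a
}

draw_frailty <- function(n, v, a, unif = NULL) {
  if (v == 0) return(rep(1, n))
  shape <- (1 - a)^2 / v
  rate <- (1 - a) / v
  if (is.null(unif)) a + rgamma(n, shape = shape, rate = rate)
  else a + stats::qgamma(unif, shape = shape, rate = rate)
}

# Solve the frailty variance inducing the target exchangeable correlation of
# ECS, by pilot simulation of the actual planting mechanism under common
# random numbers.  Deterministic given the config (fixed internal seed) and
# cached, so repeated simulations do not re-solve.
calibrate_frailty_var <- function(config, n_pilot = 12000) {
  key <- hash(list(
    config$prevalence_level0, config$prevalence_by_level,
    config$severity_log_rr, config$baseline_ecs_mean,
    config$target_within_person_corr, config$covar_log_rr,
    config$level4_implies_level3, config$level5_signature_dist,
    config$ecs_category_weights, config$n_persons,
    config$insured_pool_size, config$years, config$overlap_structure
  ))
  if (!is.null(the$frailty_cache[[key]])) return(the$frailty_cache[[key]])

  centring <- covar_centring(config)
  a_shift <- frailty_shift(config, centring)
  years <- config$years
  ny <- length(years)
  p_act <- config$prevalence_level0 * config$insured_pool_size /
    max(config$n_persons, 1)
  pats <- lapply(as.character(years), function(y) {
    level_pattern_dist(config, y)
  })
  weights <- config$ecs_category_weights
  cat_names <- unique(elixhauser_map()$category)
  weights <- weights[cat_names]

  rho_hat <- withr::with_seed(20170101L, {
    active <- matrix(runif(n_pilot * ny), n_pilot) <
      matrix(rep(p_act, each = n_pilot), n_pilot)
    maxlev <- matrix(0L, n_pilot, ny)
    for (j in seq_len(ny)) {
      idx <- which(active[, j])
      if (!length(idx)) next
      pid <- sample.int(nrow(pats[[j]]$bits), length(idx),
                        replace = TRUE, prob = pats[[j]]$probs)
      maxlev[idx, j] <- 6L - max.col(pats[[j]]$bits[pid, 5:1, drop = FALSE],
                                     ties.method = "first")
    }
    rows <- which(active, arr.ind = TRUE)
    person <- rows[, 1]
    lev <- maxlev[rows]
    # intrinsic flag count: levels 1-4 flag alcohol abuse; level 5 also
    # flags liver disease when the signature carries K70 codes
    p_k70 <- config$level5_signature_dist[["k70_only"]] +
      config$level5_signature_dist[["combination"]] * 0.6
    has_k70 <- runif(n_pilot) < p_k70
    k_int <- ifelse(lev == 5 & has_k70[person], 2, 1)
    rr <- exp(c(0, config$severity_log_rr))[lev]
    u_unif <- runif(n_pilot)
    flag_unif <- matrix(runif(length(person) * 31), length(person))
    eligible <- matrix(TRUE, length(person), 31)
    eligible[, match("alcohol_abuse", cat_names)] <- FALSE
    eligible[k_int == 2, match("liver_disease", cat_names)] <- FALSE

    function(v) {
      u <- draw_frailty(n_pilot, v, a_shift, unif = u_unif)
      mu <- u[person] * config$baseline_ecs_mean * rr
      q <- waterfill_probs(mu - k_int, eligible, weights)
      y <- k_int + rowSums(flag_unif < q)
      # residuals against the marginal (population-averaged) mean, which
      # is what the GEE working model sees; E[u] = 1
      m <- config$baseline_ecs_mean * rr
      r <- (y - m) / sqrt(m)
      phi <- sum(r^2) / length(r)
      s1 <- rowsum(r, person)
      s2 <- rowsum(r^2, person)
      ni <- as.vector(rowsum(rep(1, length(person)), person))
      sum((s1^2 - s2) / 2) / (phi * sum(ni * (ni - 1) / 2))
    }
  })

  f <- function(v) rho_hat(v) - config$target_within_person_corr
  if (f(0.02) >= 0) {
    v <- 0.02
  } else {
    v <- uniroot(f, c(0.02, 25), tol = 1e-3)$root
  }
  if (is.null(the$frailty_cache)) the$frailty_cache <- list()
  the$frailty_cache[[key]] <- v
  v
}

# ---- diagnosis generation ---------------------------------------------------

level5_pools <- function() {
  list(
    k70 = c("K70.0", "K70.1", "K70.2", "K70.3", "K70.4", "K70.9"),
    f10 = c("F10.5", "F10.6", "F10.7", "F10.8", "F10.9"),
    g62 = "G62.1",
    other = c("E24.4", "G31.2", "G72.1", "I42.6", "K29.2",
              "K85.2", "K85.20", "K86.0")
  )
}

draw_level_codes <- function(level, n) {
  out <- character(length(level))
  i1 <- level == 1L
  out[i1] <- sample(c("F10.0", "T51.0", "T51.9"), sum(i1),
                    replace = TRUE, prob = c(0.8, 0.1, 0.1))
  out[level == 2L] <- "F10.1"
  out[level == 3L] <- "F10.2"
  i4 <- level == 4L
  out[i4] <- sample(c("F10.3", "F10.4"), sum(i4),
                    replace = TRUE, prob = c(0.8, 0.2))
  out
}

# random billing attributes (setting, qualifier, quarter, dates) for n
# qualifying records in the given years
draw_record_attrs <- function(person_id, year, icd_code, config) {
  n <- length(person_id)
  outp <- runif(n) < config$outpatient_prop
  qualifier <- ifelse(outp, "confirmed",
                      sample(c("admission", "primary", "secondary"), n,
                             replace = TRUE, prob = c(0.25, 0.35, 0.4)))
  quarter <- ifelse(outp, sample.int(4L, n, replace = TRUE), NA_integer_)
  adm_off <- sample.int(350L, n, replace = TRUE) - 1L
  los <- sample.int(15L, n, replace = TRUE) - 1L
  yrs <- sort(unique(year))
  adm <- as.Date(sprintf("%d-01-01", yrs))[match(year, yrs)] + adm_off
  dis <- adm + los
  tibble(
    person_id = person_id,
    icd_code = icd_code,
    setting = ifelse(outp, "outpatient", "inpatient"),
    qualifier = qualifier,
    year = as.integer(year),
    quarter = as.integer(quarter),
    admission_date = if_else(outp, as.Date(NA), adm),
    discharge_date = if_else(outp, as.Date(NA), dis)
  )
}

#' Simulate diagnosis records with planted severity and comorbidity
#'
#' For every at-risk person-year that is "active" (planted any-AUD), emits
#' qualifying alcohol-specific records consistent with the planted severity
#' level set (withdrawal years also carry dependence codes with probability
#' `level4_implies_level3`), plus comorbidity records drawn so that the
#' person-year Elixhauser count follows a gamma-frailty Poisson-type
#' mixture with the planted severity rate ratios, plus non-qualifying
#' noise records and occasional excluded codes (R78.0 / O35.4) that
#' exercise the downstream filters.
#'
#' Running the qualifier filter and severity classifier on the result
#' recovers the planted level set of every person-year exactly, because
#' noise records never carry qualifying qualifiers and extra comorbidity
#' codes never collide with severity codes.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The [sim_config()] used for the cohort.
#' @return A list: `diagnoses` (tibble of raw billing records) and `truth`
#'   (planted ground truth, see [planted_truth()]).
#' @export
simulate_diagnoses <- function(cohort, config = sim_config()) {
  stopifnot(inherits(config, "aud_sim_config"))
  cases <- filter(cohort$persons, .data$at_risk)
  years <- config$years
  empty <- tibble(
    person_id = character(), icd_code = character(), setting = character(),
    qualifier = character(), year = integer(), quarter = integer(),
    admission_date = as.Date(character()), discharge_date = as.Date(character())
  )
  if (nrow(cases) == 0) {
    return(list(diagnoses = empty, truth = empty_truth(config)))
  }

  v <- config$frailty_var %||% calibrate_frailty_var(config)
  centring <- covar_centring(config)
  a_shift <- if (v > 0) frailty_shift(config, centring) else 0

  withr::with_seed(derive_seed(config$seed, "diagnoses"), {
    n_case <- nrow(cases)
    ny <- length(years)
    p_act <- config$prevalence_level0 * config$insured_pool_size / n_case

    # planted activity and severity-level sets
    pats <- lapply(as.character(years), function(y) {
      level_pattern_dist(config, y)
    })
    act_list <- vector("list", ny)
    for (j in seq_len(ny)) {
      on <- runif(n_case) < p_act[j]
      idx <- which(on)
      if (!length(idx)) next
      pid <- sample.int(nrow(pats[[j]]$bits), length(idx),
                        replace = TRUE, prob = pats[[j]]$probs)
      lv <- pats[[j]]$bits[pid, , drop = FALSE]
      act_list[[j]] <- tibble(
        person_id = cases$person_id[idx],
        year = years[j],
        l1 = lv[, 1] == 1, l2 = lv[, 2] == 1, l3 = lv[, 3] == 1,
        l4 = lv[, 4] == 1, l5 = lv[, 5] == 1
      )
    }
    active <- bind_rows(act_list)
    if (is.null(active) || nrow(active) == 0) {
      res <- list(diagnoses = empty,
                  truth = empty_truth(config, frailty_var = v))
      return(res)
    }
    lv_mat <- as.matrix(active[, paste0("l", 1:5)])
    active$max_level <- 6L - max.col(lv_mat[, 5:1, drop = FALSE],
                                     ties.method = "first")

    # long (person, year, level) planted truth
    pyl <- purrr::map_dfr(1:5, function(l) {
      tibble(person_id = active$person_id[lv_mat[, l]],
             year = active$year[lv_mat[, l]], level = l)
    })

    # level-5 diagnostic signature, sticky per person
    sig_groups <- draw_level5_signatures(cases$person_id, config)

    sev_records <- build_severity_records(active, pyl, sig_groups, config)

    # non-qualifying noise and excluded-code records
    noise <- build_noise_records(sev_records, config)
    excl <- build_excluded_records(active, config)

    # comorbidity planting
    com <- build_comorbidity_records(active, sev_records, cases, v, a_shift,
                                     centring, config, cohort)

    diagnoses <- arrange(
      bind_rows(sev_records, noise, excl, com$records),
      .data$person_id, .data$year, .data$icd_code, .data$setting,
      .data$qualifier, .data$quarter
    )

    truth <- list(
      person_year_levels = arrange(pyl, .data$person_id, .data$year,
                                   .data$level),
      person_years = select(
        com$active, "person_id", "year", "max_level", "mu"),
      frailty = com$frailty,
      params = list(
        prevalence_level0 = config$prevalence_level0,
        prevalence_by_level = config$prevalence_by_level,
        severity_log_rr = config$severity_log_rr,
        ecs_mean_by_level = setNames(
          config$baseline_ecs_mean * exp(c(0, config$severity_log_rr)),
          as.character(1:5)),
        target_within_person_corr = config$target_within_person_corr,
        frailty_var = v,
        frailty_shift = a_shift
      )
    )
    list(diagnoses = diagnoses, truth = truth)
  })
}

empty_truth <- function(config, frailty_var = config$frailty_var) {
  list(
    person_year_levels = tibble(person_id = character(), year = integer(),
                                level = integer()),
    person_years = tibble(person_id = character(), year = integer(),
                          max_level = integer(), mu = numeric()),
    frailty = tibble(person_id = character(), u = numeric()),
    params = list(
      prevalence_level0 = config$prevalence_level0,
      prevalence_by_level = config$prevalence_by_level,
      severity_log_rr = config$severity_log_rr,
      ecs_mean_by_level = setNames(
        config$baseline_ecs_mean * exp(c(0, config$severity_log_rr)),
        as.character(1:5)),
      target_within_person_corr = config$target_within_person_corr,
      frailty_var = frailty_var
    )
  )
}

draw_level5_signatures <- function(person_id, config) {
  n <- length(person_id)
  sig <- sample(names(config$level5_signature_dist), n, replace = TRUE,
                prob = config$level5_signature_dist)
  groups <- lapply(seq_len(n), function(i) {
    switch(sig[i],
      k70_only = "k70",
      f10_59_only = "f10",
      g62_only = "g62",
      combination = sample(c("k70", "f10", "g62", "other"),
                           size = sample(2:3, 1, prob = c(0.8, 0.2)))
    )
  })
  setNames(groups, person_id)
}

build_severity_records <- function(active, pyl, sig_groups, config) {
  pools <- level5_pools()
  n_rec <- 1L + rpois(nrow(pyl), config$extra_records_mean)
  rows <- rep(seq_len(nrow(pyl)), n_rec)
  rec <- pyl[rows, ]

  codes <- character(nrow(rec))
  not5 <- rec$level != 5L
  codes[not5] <- draw_level_codes(rec$level[not5], sum(not5))
  i5 <- which(!not5)
  if (length(i5)) {
    union_pool <- lapply(sig_groups, function(g) unlist(pools[g],
                                                        use.names = FALSE))
    pidx <- match(rec$person_id[i5], names(sig_groups))
    pool_len <- lengths(union_pool)[pidx]
    pick <- floor(runif(length(i5)) * pool_len) + 1
    codes[i5] <- mapply(function(p, k) union_pool[[p]][k], pidx, pick)
  }
  rec$icd_code <- codes

  # guarantee every signature group appears in the first level-5 year, so
  # the study-window level-5 composition matches the planted signatures
  l5_first <- pyl |>
    filter(.data$level == 5L) |>
    group_by(.data$person_id) |>
    summarise(year = min(.data$year), .groups = "drop")
  if (nrow(l5_first)) {
    sig_long <- tibble(
      person_id = rep(names(sig_groups), lengths(sig_groups)),
      group = unlist(sig_groups, use.names = FALSE)
    )
    extra <- inner_join(l5_first, sig_long, by = "person_id")
    glen <- lengths(pools)[extra$group]
    gpick <- floor(runif(nrow(extra)) * glen) + 1
    extra$icd_code <- mapply(function(g, k) pools[[g]][k], extra$group, gpick)
    extra$level <- 5L
    rec <- bind_rows(rec, select(extra, "person_id", "year", "level",
                                 "icd_code"))
  }

  draw_record_attrs(rec$person_id, rec$year, rec$icd_code, config)
}

build_noise_records <- function(sev_records, config) {
  p_noise <- ifelse(sev_records$setting == "outpatient",
                    config$noise_outpatient, config$noise_inpatient)
  keep <- runif(nrow(sev_records)) < p_noise
  noise <- sev_records[keep, ]
  if (nrow(noise) == 0) return(noise)
  outp <- noise$setting == "outpatient"
  noise$qualifier[outp] <- sample(
    c("exclusionary", "suspecting", "symptomless"), sum(outp),
    replace = TRUE)
  noise$qualifier[!outp] <- sample(c("surgery", "follow_up"), sum(!outp),
                                   replace = TRUE)
  noise
}

build_excluded_records <- function(active, config) {
  keep <- runif(nrow(active)) < config$excluded_code_rate
  if (!any(keep)) {
    return(tibble(person_id = character(), icd_code = character(),
                  setting = character(), qualifier = character(),
                  year = integer(), quarter = integer(),
                  admission_date = as.Date(character()),
                  discharge_date = as.Date(character())))
  }
  code <- sample(c("R78.0", "O35.4"), sum(keep), replace = TRUE,
                 prob = c(0.97, 0.03))
  tibble(
    person_id = active$person_id[keep],
    icd_code = code,
    setting = "outpatient",
    qualifier = "confirmed",
    year = as.integer(active$year[keep]),
    quarter = sample.int(4L, sum(keep), replace = TRUE),
    admission_date = as.Date(NA),
    discharge_date = as.Date(NA)
  )
}

build_comorbidity_records <- function(active, sev_records, cases, v, a_shift,
                                      centring, config, cohort) {
  cat_names <- unique(elixhauser_map()$category)
  weights <- config$ecs_category_weights[cat_names]
  if (anyNA(weights)) {
    abort_config("ecs_category_weights",
                 "must name every Elixhauser category")
  }

  # frailty per at-risk person
  u <- draw_frailty(nrow(cases), v, a_shift)
  frailty <- tibble(person_id = cases$person_id, u = u)

  # covariate multiplier (identity when all planted effects are zero)
  mult <- rep(1, nrow(active))
  if (centring$active) {
    eff <- config$covar_log_rr
    info <- cases[match(active$person_id, cases$person_id), ]
    ag <- as.integer(age_group(age_in_year(info$birth_year, active$year)))
    emp <- resolve_employment(
      filter(cohort$employment_spells,
             .data$person_id %in% active$person_id),
      config$years
    )
    emp_status <- emp$employment[match(
      paste(active$person_id, active$year),
      paste(emp$person_id, emp$year))]
    lp <- ifelse(info$sex == "female", eff$sex_female, 0) +
      eff$age_group[ag] +
      eff$employment[match(emp_status, employment_levels())] +
      eff$year[as.character(active$year)]
    mult <- exp(lp - centring$cbar)
  }

  rr <- exp(c(0, config$severity_log_rr))[active$max_level]
  mu <- u[match(active$person_id, cases$person_id)] *
    config$baseline_ecs_mean * rr * mult

  # intrinsic Elixhauser flags carried by the severity codes themselves
  hits <- match_elixhauser(unique(sev_records$icd_code))
  sev_cats <- sev_records |>
    select("person_id", "year", "icd_code") |>
    inner_join(hits, by = "icd_code", relationship = "many-to-many") |>
    distinct(.data$person_id, .data$year, .data$category)
  key_active <- paste(active$person_id, active$year)
  eligible <- matrix(TRUE, nrow(active), 31,
                     dimnames = list(NULL, cat_names))
  if (nrow(sev_cats)) {
    ij <- cbind(match(paste(sev_cats$person_id, sev_cats$year), key_active),
                match(sev_cats$category, cat_names))
    eligible[ij] <- FALSE
  }
  k_int <- 31 - rowSums(eligible)

  q <- waterfill_probs(mu - k_int, eligible, weights)
  flags <- matrix(runif(length(q)), nrow(q)) < q

  idx <- which(flags, arr.ind = TRUE)
  safe <- elix_safe_pool()
  pool_by_cat <- split(safe$icd_code, safe$category)
  missing_pool <- setdiff(cat_names, names(pool_by_cat))
  if (length(missing_pool)) {
    abort(paste0("no collision-free synthetic codes for category: ",
                 paste(missing_pool, collapse = ", ")))
  }
  cat_drawn <- cat_names[idx[, 2]]
  pool_len <- lengths(pool_by_cat)[cat_drawn]
  pick <- floor(runif(length(cat_drawn)) * pool_len) + 1
  code <- mapply(function(cc, k) pool_by_cat[[cc]][k], cat_drawn, pick,
                 USE.NAMES = FALSE)

  records <- draw_record_attrs(active$person_id[idx[, 1]],
                               active$year[idx[, 1]], code, config)
  active$mu <- mu
  list(records = records, active = active, frailty = frailty)
}
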