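qualifying_outpatient <- function() "confirmed"
qualifying_inpatient <- function() c("admission", "primary", "secondary")
known_outpatient <- function() c("confirmed", "exclusionary", "suspecting",
                                 "symptomless")
known_inpatient <- function() c("admission", "primary", "secondary",
                                "surgery", "follow_up")

#' Filter raw diagnoses to qualifying records
#'
#' Keeps outpatient records with a `confirmed` qualifier and inpatient
#' records with an `admission`, `primary` or `secondary` qualifier;
#' everything else (exclusionary / suspecting / symptomless outpatient
#' diagnoses, surgery and follow-up inpatient diagnoses) is dropped.
#' Codes on the exclusion list (O35.4 fetal alcohol damage, R78.0 alcohol
#' in blood) are dropped regardless of qualifier.  Records with a
#' qualifier outside the known vocabulary are dropped with a warning
#' rather than failing, to tolerate dialect variation in claims extracts.
#'
#' @param diagnoses Tibble of raw diagnosis records with columns
#'   `person_id`, `icd_code`, `setting`, `qualifier` (and date columns).
#' @return The qualifying records, with a `drop_log` attribute: a tibble
#'   of dropped-record counts by reason.  Dropped + kept = input rows.
#' @export
filter_diagnoses <- function(diagnoses) {
  d <- mutate(diagnoses, icd_code = normalize_icd(.data$icd_code))
  known <- (d$setting == "outpatient" & d$qualifier %in% known_outpatient()) |
    (d$setting == "inpatient" & d$qualifier %in% known_inpatient())
  if (any(!known)) {
    warn(sprintf("%d record(s) with unknown qualifier dropped", sum(!known)))
  }
  qualifying <- (d$setting == "outpatient" &
                   d$qualifier %in% qualifying_outpatient()) |
    (d$setting == "inpatient" & d$qualifier %in% qualifying_inpatient())
  excluded <- d$icd_code %in% excluded_codes()

  kept <- d[known & qualifying & !excluded, ]
  drop_log <- tibble(
    reason = c("unknown_qualifier", "non_qualifying_qualifier",
               "excluded_code"),
    n = c(sum(!known),
          sum(known & !qualifying),
          sum(known & qualifying & excluded))
  )
  attr(kept, "drop_log") <- drop_log
  kept
}

#' Median day of a calendar quarter
#'
#' The date assigned to quarterly outpatient diagnoses.  For quarters with
#' an even number of days the earlier of the two middle days is used.
#'
#' @param year,quarter Integer vectors (quarter in 1-4).
#' @return A Date vector.
#' @export
#' @examples
#' quarter_median_day(2017, 1) # "2017-02-14" (day 45 of 90)
#' quarter_median_day(2020, 1) # "2020-02-15" (day 46 of 91, leap year)
quarter_median_day <- function(year, quarter) {
  if (any(is.na(quarter)) || any(!quarter %in% 1:4)) {
    abort("quarter_median_day(): `quarter` must be in 1..4")
  }
  start <- as.Date(sprintf("%d-%02d-01", year, 3 * (quarter - 1) + 1))
  nxt <- as.Date(sprintf(
    "%d-%02d-01",
    year + (quarter == 4), ifelse(quarter == 4, 1, 3 * quarter + 1)
  ))
  ndays <- as.integer(nxt - start)
  start + (floor((ndays + 1) / 2) - 1)
}

#' Assign a calendar date to each qualifying diagnosis
#'
#' Outpatient diagnoses are registered per quarter and dated to the median
#' day of the quarter; inpatient diagnoses are dated to the admission day.
#'
#' @param diagnoses Filtered diagnosis records.
#' @return The input with an `assigned_date` column.
#' @export
assign_dates <- function(diagnoses) {
  outp <- diagnoses$setting == "outpatient"
  if (any(outp & (is.na(diagnoses$quarter) |
                    !diagnoses$quarter %in% 1:4))) {
    abort("assign_dates(): outpatient records need a quarter in 1..4")
  }
  date <- as.Date(rep(NA, nrow(diagnoses)))
  if (any(outp)) {
    date[outp] <- quarter_median_day(diagnoses$year[outp],
                                     diagnoses$quarter[outp])
  }
  if (any(!outp)) {
    if (any(is.na(diagnoses$admission_date[!outp]))) {
      abort("assign_dates(): inpatient records need an admission_date")
    }
    date[!outp] <- diagnoses$admission_date[!outp]
  }
  out <- mutate(diagnoses, assigned_date = date)
  attr(out, "drop_log") <- NULL
  out
}

#' Classify person-periods into AUD severity levels
#'
#' Maps each person-period to its (possibly overlapping) set of AUD
#' severity levels: level `l` is assigned iff at least one qualifying
#' diagnosis in the period carries a code from level `l` of the
#' [severity_code_map()].  A person with both an F10.2 and an F10.3
#' diagnosis is therefore classified into levels 3 *and* 4.  Level 0
#' ("any AUD") is implicit: it holds whenever the level set is non-empty.
#'
#' @param dated_diagnoses Filtered, dated diagnoses (see
#'   [filter_diagnoses()], [assign_dates()]).
#' @param period `"year"` (one set per person-year, the default) or
#'   `"window"` (one set per person over the whole study window).
#' @return A long tibble with columns `person_id`, `year` (omitted for
#'   `period = "window"`) and `level` (integer 1-5); one row per assigned
#'   level, no duplicates.  Persons with no qualifying alcohol-specific
#'   diagnosis have no rows.
#' @export
classify_severity <- function(dated_diagnoses, period = c("year", "window")) {
  period <- match.arg(period)
  map <- severity_code_map()
  hit <- dated_diagnoses |>
    mutate(icd_code = normalize_icd(.data$icd_code)) |>
    inner_join(select(map, "code", "level"),
               by = c(icd_code = "code"))
  if (period == "year") {
    out <- distinct(hit, .data$person_id, .data$year, .data$level)
    arrange(out, .data$person_id, .data$year, .data$level)
  } else {
    out <- distinct(hit, .data$person_id, .data$level)
    arrange(out, .data$person_id, .data$level)
  }
}

#' Composition of severity level 5 by diagnostic code group
#'
#' Partitions the persons ever classified into level 5 by which code
#' groups their level-5 diagnoses come from: alcoholic liver disease only
#' (`k70_only`), higher-order F10.5-F10.9 diagnoses only (`f10_59_only`),
#' alcoholic polyneuropathy only (`g62_only`), or any combination /
#' other level-5 code (`combination_or_other`).  The partition is
#' mutually exclusive and exhaustive; shares sum to 1.
#'
#' @param dated_diagnoses Filtered, dated diagnoses for the study window.
#' @return A tibble with columns `group`, `n`, `share`.
#' @export
level5_composition <- function(dated_diagnoses) {
  pools <- level5_pools()
  map <- severity_code_map()
  l5 <- dated_diagnoses |>
    mutate(icd_code = normalize_icd(.data$icd_code)) |>
    inner_join(select(filter(map, .data$level == 5L), "code"),
               by = c(icd_code = "code")) |>
    distinct(.data$person_id, .data$icd_code)
  grp <- dplyr::case_when(
    l5$icd_code %in% pools$k70 ~ "k70",
    l5$icd_code %in% pools$f10 ~ "f10",
    l5$icd_code %in% pools$g62 ~ "g62",
    TRUE ~ "other"
  )
  per_person <- tibble(person_id = l5$person_id, grp = grp) |>
    distinct() |>
    group_by(.data$person_id) |>
    summarise(groups = paste(sort(unique(.data$grp)), collapse = "+"),
              .groups = "drop")
  lab <- dplyr::case_when(
    per_person$groups == "k70" ~ "k70_only",
    per_person$groups == "f10" ~ "f10_59_only",
    per_person$groups == "g62" ~ "g62_only",
    TRUE ~ "combination_or_other"
  )
  out <- tibble(group = factor(lab, levels = c(
    "k70_only", "f10_59_only", "g62_only", "combination_or_other"))) |>
    count(.data$group, .drop = FALSE, name = "n") |>
    mutate(share = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0,
           group = as.character(.data$group))
  out
}
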