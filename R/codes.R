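#' AUD severity code map
#'
#' The five-level grouping of alcohol-specific ICD-10 codes used to
#' classify AUD severity.  Level 1 captures acute intoxication (F10.0,
#' T51.0, T51.9), level 2 harmful use (F10.1), level 3 dependence (F10.2),
#' level 4 withdrawal with or without delirium (F10.3, F10.4), and level 5
#' chronic end-organ damage (alcoholic liver disease K70.x, pancreatitis,
#' higher-order F10 diagnoses, and related codes).  Level 0 ("any AUD") is
#' the union of levels 1-5 and is not represented by its own codes.
#'
#' Matching against this map is exact on normalised codes (trimmed,
#' upper-cased, dot retained); there is no prefix wildcarding.
#'
#' @return A tibble with columns `code`, `level` (integer 1-5) and `label`.
#' @export
#' @examples
#' severity_code_map()
severity_code_map <- function() {
  if (is.null(the$severity_map)) {
    path <- system.file("extdata", "severity_codes.csv", package = "audsev")
    map <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             code = readr::col_character(),
                             level = readr::col_integer(),
                             label = readr::col_character()
                           ))
    map$code <- normalize_icd(map$code)
    the$severity_map <- map
  }
  the$severity_map
}

#' Alcohol-specific codes excluded from the severity classification
#'
#' Fetal damage due to maternal alcohol use (O35.4) and the mere presence
#' of alcohol in the blood (R78.0) are not counted as AUD diagnoses.
#'
#' @return Character vector of excluded ICD-10 codes.
#' @export
excluded_codes <- function() c("O35.4", "R78.0")

#' Elixhauser comorbidity category map (Quan ICD-10 adaptation)
#'
#' The 31 Elixhauser comorbidity categories with their ICD-10 code stems,
#' following the Quan et al. ICD-10 coding algorithm.  A diagnosis code is
#' assigned to a category when one of the category's stems is a prefix of
#' the (normalised) code, the usual convention for comorbidity flagging on
#' claims data.  Exactly one category (`alcohol_abuse`) is marked as
#' alcohol-specific; the remaining 30 categories define the non-alcohol
#' comorbidity count.
#'
#' The map is shipped as a plain CSV and can be swapped via `path` to test
#' sensitivity to the coding algorithm.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `category`, `icd_code`, `alcohol_specific`.
#' @return A tibble with columns `category`, `icd_code`, `alcohol_specific`.
#' @export
elixhauser_map <- function(path = NULL) {
  if (!is.null(path)) {
    map <- readr::read_csv(path, show_col_types = FALSE)
  } else {
    if (!is.null(the$elix_map)) return(the$elix_map)
    map <- readr::read_csv(
      system.file("extdata", "elixhauser_icd10.csv", package = "audsev"),
      show_col_types = FALSE,
      col_types = readr::cols(
        category = readr::col_character(),
        icd_code = readr::col_character(),
        alcohol_specific = readr::col_logical()
      )
    )
  }
  map$icd_code <- normalize_icd(map$icd_code)
  stopifnot(
    length(unique(map$category)) == 31,
    sum(tapply(map$alcohol_specific, map$category, any)) == 1
  )
  if (is.null(path)) the$elix_map <- map
  map
}

# Match a vector of ICD codes against Elixhauser stems by prefix.
# Returns a tibble (icd_code, category) with one row per (code, category) hit.
match_elixhauser <- function(codes, map = elixhauser_map()) {
  codes <- unique(normalize_icd(codes))
  hits <- purrr::map_dfr(seq_len(nrow(map)), function(i) {
    hit <- startsWith(codes, map$icd_code[i])
    if (!any(hit)) return(NULL)
    tibble(icd_code = codes[hit], category = map$category[i])
  })
  if (nrow(hits) == 0) {
    return(tibble(icd_code = character(), category = character()))
  }
  distinct(hits)
}

# Elixhauser stems usable as synthetic "extra comorbidity" codes: stems that
# (a) do not collide with severity or excluded codes in either prefix
# direction, and (b) map back to exactly one category under the prefix
# matcher, so a planted category flag yields exactly one observed flag.
elix_safe_pool <- function(map = elixhauser_map()) {
  if (!is.null(the$elix_safe)) return(the$elix_safe)
  sev <- c(severity_code_map()$code, excluded_codes())
  collides <- vapply(map$icd_code, function(e) {
    any(startsWith(sev, e) | startsWith(e, sev))
  }, logical(1))
  n_cat <- vapply(map$icd_code, function(e) {
    length(unique(map$category[vapply(map$icd_code, function(s)
      startsWith(e, s), logical(1))]))
  }, integer(1))
  safe <- map[!collides & n_cat == 1L, c("category", "icd_code")]
  the$elix_safe <- safe
  safe
}
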