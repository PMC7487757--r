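#' Derive age group and birth cohort
#'
#' Age at survey is `wave_year - birth_year` (the questionnaires carry no
#' month-level detail). Age groups are 18--34, 35--54 and 55+ years, all
#' boundaries inclusive; birth cohorts are <1900, 1900--1919, 1920--1939 and
#' 1940--1957, endpoints inclusive. Both are pure functions of
#' `(wave_year, birth_year)`, so re-derivation is idempotent.
#'
#' @param wave_year,birth_year Integer vectors (recycled to common length).
#' @return `derive_age_group()` and `derive_birth_cohort()` return factors
#'   with the reference level (18--34, <1900) first.
#' @export
derive_age_group <- function(wave_year, birth_year) {
  age <- wave_year - birth_year
  if (any(age < 18)) {
    stop("age at survey below 18 for some rows", call. = FALSE)
  }
  cut(age, breaks = c(18, 35, 55, Inf), right = FALSE,
      labels = c("18-34", "35-54", "55+"))
}

#' @rdname derive_age_group
#' @export
derive_birth_cohort <- function(wave_year, birth_year) {
  if (any(birth_year > 1957)) {
    stop("birth_year after 1957 outside the cohort", call. = FALSE)
  }
  cut(birth_year, breaks = c(-Inf, 1900, 1920, 1940, 1958), right = FALSE,
      labels = c("<1900", "1900-1919", "1920-1939", "1940-1957"))
}

age_group_levels <- c("18-34", "35-54", "55+")
birth_cohort_levels <- c("<1900", "1900-1919", "1920-1939", "1940-1957")
gender_levels <- c("female", "male")

#' Validate and enrich per-response cohort records
#'
#' Checks a raw response table (one row per questionnaire response) and
#' attaches derived covariates and the censoring interval implied by the
#' wave's response scheme. Raw columns: `subject_id`, `pair_id`, `wave_year`,
#' `gender` (`"female"`/`"male"`), `birth_year`, `response_category`.
#'
#' Validation rejects, with the offending row numbers: unknown wave years,
#' categories outside the wave's scheme, pairs with more than two subjects,
#' and pairs whose members differ in gender or birth year (twin pairs are
#' same-gender and share a birth year; size-1 "pairs" are allowed because the
#' 1975 survey also included non-twins).
#'
#' @param data Data frame of raw response records.
#' @param schemes Scheme table, as produced by [sleep_schemes()].
#' @return A tibble in input row order with the raw columns plus
#'   `age_at_survey`, `age_group`, `birth_cohort`, `left`, `right`, `kind`.
#' @export
as_sleep_responses <- function(data, schemes = sleep_schemes()) {
  required <- c("subject_id", "pair_id", "wave_year", "gender", "birth_year",
                "response_category")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) {
    return(tibble::tibble(
      subject_id = character(), pair_id = character(),
      wave_year = integer(), gender = factor(character(), gender_levels),
      birth_year = integer(), response_category = character(),
      age_at_survey = integer(),
      age_group = factor(character(), age_group_levels),
      birth_cohort = factor(character(), birth_cohort_levels),
      left = double(), right = double(), kind = character()))
  }
  data$subject_id <- as.character(data$subject_id)
  data$pair_id <- as.character(data$pair_id)
  data$wave_year <- as.integer(data$wave_year)
  data$birth_year <- as.integer(data$birth_year)
  data$response_category <- as.character(data$response_category)

  wt <- wave_table()
  bad <- which(!data$wave_year %in% wt$wave_year)
  if (length(bad)) {
    stop("unknown wave_year at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!data$gender %in% gender_levels)
  if (length(bad)) {
    stop("gender must be 'female' or 'male'; bad row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  sid <- scheme_for_wave(data$wave_year)
  for (s in unique(sid)) {
    rows <- scheme_rows(s, schemes)
    bad <- which(sid == s & !data$response_category %in% rows$label)
    if (length(bad)) {
      stop("response_category not in scheme ", s, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  # pair structure: at most two subjects, shared gender and birth year
  per_pair <- dplyr::summarise(
    dplyr::group_by(data, .data$pair_id),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    n_gender = dplyr::n_distinct(.data$gender),
    n_birth = dplyr::n_distinct(.data$birth_year), .groups = "drop")
  offending <- per_pair$pair_id[per_pair$n_subjects > 2 |
                                  per_pair$n_gender > 1 | per_pair$n_birth > 1]
  if (length(offending)) {
    bad <- which(data$pair_id %in% offending)
    stop("invalid pair structure (size > 2 or mixed gender/birth year) ",
         "for pair(s) ", paste(utils::head(offending, 3), collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }

  data$gender <- factor(data$gender, gender_levels)
  data$age_at_survey <- data$wave_year - data$birth_year
  data$age_group <- derive_age_group(data$wave_year, data$birth_year)
  data$birth_cohort <- derive_birth_cohort(data$wave_year, data$birth_year)
  iv <- purrr::map_dfr(split(seq_len(nrow(data)), sid), function(idx) {
    m <- map_response(data$response_category[idx], sid[idx[1]], schemes)
    m$row <- idx
    m
  })
  iv <- iv[order(iv$row), ]
  data$left <- iv$left
  data$right <- iv$right
  data$kind <- iv$kind
  data
}

#' Read and write per-response cohort records
#'
#' CSV dialect: comma-separated, UTF-8, mandatory header, category labels
#' quoted verbatim. `read_responses()` validates and enriches every row via
#' [as_sleep_responses()]; `write_responses()` writes only the six raw
#' columns, so `read_responses(write_responses(x))` round-trips losslessly.
#'
#' @param path CSV file path.
#' @param schemes Scheme table, as produced by [sleep_schemes()].
#' @return `read_responses()` returns the enriched tibble;
#'   `write_responses()` returns `path` invisibly.
#' @export
read_responses <- function(path, schemes = sleep_schemes()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    pair_id = readr::col_character(),
    wave_year = readr::col_integer(),
    gender = readr::col_character(),
    birth_year = readr::col_integer(),
    response_category = readr::col_character()), progress = FALSE)
  as_sleep_responses(raw, schemes)
}

#' @param data Response records (raw or enriched).
#' @rdname read_responses
#' @export
write_responses <- function(data, path) {
  cols <- c("subject_id", "pair_id", "wave_year", "gender", "birth_year",
            "response_category")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data[, cols]
  out$gender <- as.character(out$gender)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
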