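#' Response schemes for the four survey waves
#'
#' Each mailed questionnaire offered a fixed set of ordinal sleep-duration
#' alternatives. The 1975 wave used seven alternatives spaced one hour apart
#' (`"coarse1975"`); the 1981, 1990 and 2011 waves used the same nine
#' alternatives spaced half an hour apart (`"half_hour"`). A scheme maps each
#' category label to a censoring interval on the latent duration axis:
#' interior categories are centred on their stated value (respondents round to
#' the nearest offered value), the lowest category is left-censored at 0 and
#' the highest right-censored at infinity, so the intervals tile
#' \eqn{(0, \infty)} with no gaps.
#'
#' @return A tibble with one row per category and columns
#'   `scheme_id`, `label`, `left`, `right` (hours; `Inf` for the open top
#'   category), `kind` (`"interval"`, `"left_censored"`, `"right_censored"`)
#'   and `stated` (the stated value printed on the questionnaire, `NA` for the
#'   open-ended categories).
#' @examples
#' sleep_schemes()
#' @export
sleep_schemes <- function() {
  coarse <- tibble::tibble(
    scheme_id = "coarse1975",
    label = c("less than 4 h", "5", "6", "7", "8", "9", "10 h or more"),
    left  = c(0, 4.5, 5.5, 6.5, 7.5, 8.5, 9.5),
    right = c(4.5, 5.5, 6.5, 7.5, 8.5, 9.5, Inf),
    stated = c(NA, 5, 6, 7, 8, 9, NA)
  )
  half <- tibble::tibble(
    scheme_id = "half_hour",
    label = c("6 h or less", "6.5", "7", "7.5", "8", "8.5", "9", "9.5",
              "10 h or more"),
    left  = c(0, seq(6.25, 9.75, by = 0.5)),
    right = c(seq(6.25, 9.75, by = 0.5), Inf),
    stated = c(NA, seq(6.5, 9.5, by = 0.5), NA)
  )
  out <- dplyr::bind_rows(coarse, half)
  out$kind <- dplyr::case_when(
    out$left == 0 ~ "left_censored",
    is.infinite(out$right) ~ "right_censored",
    TRUE ~ "interval"
  )
  out[, c("scheme_id", "label", "left", "right", "kind", "stated")]
}

# wave year -> scheme id; also carries eligibility and response rates used as
# simulation defaults (per-wave participation probabilities)
wave_table <- function() {
  tibble::tibble(
    wave_year = c(1975L, 1981L, 1990L, 2011L),
    scheme_id = c("coarse1975", "half_hour", "half_hour", "half_hour"),
    birth_min = c(1880L, 1880L, 1930L, 1945L),
    birth_max = c(1957L, 1957L, 1957L, 1957L),
    response_rate = c(0.89, 0.84, 0.77, 0.72)
  )
}

#' Survey wave definitions
#'
#' The four questionnaire waves with their response scheme, birth-year
#' eligibility window and response rate (used as the default participation
#' probability when simulating cohorts). Eligibility: the 1975 and 1981 waves
#' covered the whole cohort (born up to 1957, aged 18 or more at the survey);
#' the 1990 wave was restricted to pairs born 1930--1957 and the 2011 wave to
#' those born 1945--1957.
#'
#' @return A tibble with columns `wave_year`, `scheme_id`, `birth_min`,
#'   `birth_max`, `response_rate`.
#' @export
survey_waves <- function() wave_table()

scheme_rows <- function(scheme_id, schemes = sleep_schemes()) {
  rows <- schemes[schemes$scheme_id == scheme_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown scheme_id: ", scheme_id, call. = FALSE)
  }
  rows
}

scheme_for_wave <- function(wave_year, schemes = sleep_schemes()) {
  wt <- wave_table()
  i <- match(as.integer(wave_year), wt$wave_year)
  if (anyNA(i)) {
    stop("unknown wave_year: ",
         paste(unique(wave_year[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  wt$scheme_id[i]
}

#' Map response categories to censoring intervals
#'
#' Converts ordinal category labels to `(left, right]`-style censoring
#' intervals in hours under a response scheme. The half-open `[left, right)`
#' convention is immaterial for a continuous latent model: likelihood
#' contributions are `S(left) - S(right)`.
#'
#' @param label Character vector of category labels.
#' @param scheme_id `"coarse1975"` or `"half_hour"`.
#' @param schemes Scheme table, as produced by [sleep_schemes()].
#' @return A tibble with columns `label`, `left`, `right`, `kind`.
#' @examples
#' map_response("8", "half_hour")
#' map_response("less than 4 h", "coarse1975")
#' @export
map_response <- function(label, scheme_id, schemes = sleep_schemes()) {
  rows <- scheme_rows(scheme_id, schemes)
  i <- match(label, rows$label)
  if (anyNA(i)) {
    stop("unknown response category for scheme ", scheme_id, ": ",
         paste(unique(label[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(label = label, left = rows$left[i], right = rows$right[i],
                 kind = rows$kind[i])
}

#' Discretize latent durations into response categories
#'
#' Inverse of [map_response()]: finds the unique category whose interval
#' contains each duration, under the half-open `[left, right)` convention.
#'
#' @param t Numeric vector of durations in hours, strictly positive.
#' @inheritParams map_response
#' @return Character vector of category labels.
#' @examples
#' discretize_duration(c(7.6, 11), "half_hour")
#' @export
discretize_duration <- function(t, scheme_id, schemes = sleep_schemes()) {
  if (any(!is.finite(t) | t <= 0)) {
    stop("durations must be finite and positive", call. = FALSE)
  }
  rows <- scheme_rows(scheme_id, schemes)
  # categories tile (0, Inf); findInterval on left endpoints gives the tile
  idx <- findInterval(t, rows$left)
  rows$label[idx]
}

#' Category midpoints for descriptive coding
#'
#' Assigns each category a single representative value in hours: interior
#' categories take their stated value; open-ended categories take a policy
#' value. The default `boundary_value` policy codes "less than 4 h" as 4.0,
#' "6 h or less" as 6.0 and "10 h or more" as 10.0 — the boundary value the
#' label names. Midpoint coding is used only for descriptive means and trend
#' statistics, never by the likelihood.
#'
#' @inheritParams map_response
#' @param policy Open-category policy; only `"boundary_value"` is built in.
#' @return Numeric vector of hours.
#' @examples
#' category_midpoint(c("7.5", "10 h or more"), "half_hour")
#' @export
category_midpoint <- function(label, scheme_id, policy = "boundary_value",
                              schemes = sleep_schemes()) {
  policy <- match.arg(policy, "boundary_value")
  rows <- scheme_rows(scheme_id, schemes)
  i <- match(label, rows$label)
  if (anyNA(i)) {
    stop("unknown response category for scheme ", scheme_id, ": ",
         paste(unique(label[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  boundary <- ifelse(rows$kind[i] == "left_censored", rows$right[i] -
                       ifelse(rows$scheme_id[i] == "coarse1975", 0.5, 0.25),
                     rows$left[i] +
                       ifelse(rows$scheme_id[i] == "coarse1975", 0.5, 0.25))
  ifelse(is.na(rows$stated[i]), boundary, rows$stated[i])
}

#' Read or write a scheme table as JSON
#'
#' Schemes are serializable so alternative boundary choices can be explored
#' without code changes. The JSON is a flat array of category records with
#' fields `scheme_id`, `label`, `left`, `right`, `kind`, `stated`; `right`
#' may be the string `"Inf"`.
#'
#' @param schemes Scheme tibble as from [sleep_schemes()].
#' @param path File path.
#' @return `read_schemes()` returns the scheme tibble; `write_schemes()`
#'   returns `path` invisibly.
#' @export
write_schemes <- function(schemes, path) {
  out <- schemes
  out$right <- ifelse(is.infinite(out$right), "Inf", as.character(out$right))
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_schemes
#' @export
read_schemes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::as_tibble(raw)
  out$right <- as.numeric(out$right)
  out$left <- as.numeric(out$left)
  if (!"stated" %in% names(out)) out$stated <- NA_real_
  out$stated <- as.numeric(out$stated)
  validate_schemes(out)
  out[, c("scheme_id", "label", "left", "right", "kind", "stated")]
}

# tiling invariant: per scheme, intervals are disjoint, ordered and cover
# (0, Inf): first left = 0, last right = Inf, each right equals next left
validate_schemes <- function(schemes) {
  for (sid in unique(schemes$scheme_id)) {
    rows <- schemes[schemes$scheme_id == sid, , drop = FALSE]
    rows <- rows[order(rows$left), , drop = FALSE]
    if (rows$left[1] != 0 || !is.infinite(rows$right[nrow(rows)]) ||
        any(rows$right[-nrow(rows)] != rows$left[-1]) ||
        any(rows$left >= rows$right)) {
      stop("scheme ", sid, " does not tile (0, Inf)", call. = FALSE)
    }
    if (anyDuplicated(rows$label)) {
      stop("scheme ", sid, " has duplicate labels", call. = FALSE)
    }
  }
  invisible(schemes)
}
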