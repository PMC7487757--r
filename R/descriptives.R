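#' Descriptive summaries of midpoint-coded sleep duration
#'
#' Means and standard deviations of midpoint-coded responses by stratum,
#' mirroring the published wave-by-gender and wave-by-age-group summary
#' table. Midpoint coding assigns each category its stated value and each
#' open-ended category the policy value (see [category_midpoint()]); it
#' introduces a discretization bias bounded by half the category width and
#' is never used by the likelihood. Strata that exist in the design but
#' collect no observations (for example the youngest age group in the last
#' wave, which only surveyed those born 1945--1957) are emitted with
#' `n = 0` and missing mean/SD.
#'
#' @param data Enriched response tibble (see [as_sleep_responses()]).
#' @param grouping One of `"wave_gender"`, `"wave_age_group"`, `"gender"`,
#'   `"age_group"`; the `wave_*` groupings cross each stratum with the
#'   survey year.
#' @param policy Open-category policy, passed to [category_midpoint()].
#' @return A tibble with columns `wave_year` (`NA` for ungrouped-by-wave
#'   summaries), `stratum`, `n`, `mean_hours`, `sd_hours`.
#' @export
summarize_sleep <- function(data, grouping = c("wave_gender",
                                               "wave_age_group", "gender",
                                               "age_group"),
                            policy = "boundary_value") {
  grouping <- match.arg(grouping)
  if (nrow(data) == 0L) stop("empty data", call. = FALSE)
  sid <- scheme_for_wave(data$wave_year)
  data$midpoint <- NA_real_
  for (s in unique(sid)) {
    idx <- sid == s
    data$midpoint[idx] <- category_midpoint(data$response_category[idx], s,
                                            policy)
  }
  strat_col <- if (grouping %in% c("wave_gender", "gender")) "gender"
               else "age_group"
  by_wave <- grouping %in% c("wave_gender", "wave_age_group")
  strat_levels <- if (strat_col == "gender") gender_levels
                  else age_group_levels

  grid <- if (by_wave) {
    tidyr::expand_grid(wave_year = sort(unique(data$wave_year)),
                       stratum = strat_levels)
  } else {
    tibble::tibble(wave_year = NA_integer_, stratum = strat_levels)
  }
  data$stratum <- as.character(data[[strat_col]])
  keys <- if (by_wave) c("wave_year", "stratum") else "stratum"
  agg <- dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))),
    n = dplyr::n(),
    mean_hours = mean(.data$midpoint),
    sd_hours = stats::sd(.data$midpoint), .groups = "drop")
  out <- dplyr::left_join(grid, agg, by = keys)
  out$n[is.na(out$n)] <- 0L
  out
}

#' Linear trend in minutes per year of follow-up
#'
#' Converts a change in mean sleep duration between two survey years into
#' minutes lost per year of follow-up:
#' `(mean_first - mean_last) * 60 / (year_last - year_first)`. Positive
#' values indicate a decrease in sleep duration.
#'
#' @param mean_first,mean_last Mean durations in hours at the two waves.
#' @param year_first,year_last Calendar years, `year_last > year_first`.
#' @return Minutes per year (vectorised).
#' @examples
#' trend_minutes_per_year(7.57, 7.39, 1975, 2011)  # 0.3 min/year
#' @export
trend_minutes_per_year <- function(mean_first, mean_last, year_first,
                                   year_last) {
  if (any(year_last <= year_first)) {
    stop("year_last must be after year_first", call. = FALSE)
  }
  (mean_first - mean_last) * 60 / (year_last - year_first)
}
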