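#' Default generating parameters for synthetic cohorts
#'
#' Hazard ratios for the six non-reference factor levels are set to the
#' published point estimates for this cohort (birth cohorts 1900--1919,
#' 1920--1939, 1940--1957: 1.11, 1.41, 1.62; age groups 35--54, 55+:
#' 1.24, 1.23; male: 1.13). The shape and intercept are calibrated so the
#' reference stratum (female, aged 18--34, born before 1900) has a
#' zero-frailty model mean of 7.69 h and SD of 0.9 h: the shape solves the
#' Weibull coefficient-of-variation equation and the intercept then matches
#' the mean in closed form. Frailty SDs default to 0.25 (pair) and 0.20
#' (individual); the source analysis does not report frailty variances, so
#' these are this package's own choices of plausible within-pair and
#' within-person correlation.
#'
#' @param mean_hours,sd_hours Reference-stratum latent mean and SD (hours).
#' @param sigma_pair,sigma_ind Frailty SDs on the log-hazard scale.
#' @return A [weibull_frailty_params()] object.
#' @examples
#' exp(default_truth()$beta)   # the six generating hazard ratios
#' @export
default_truth <- function(mean_hours = 7.69, sd_hours = 0.9,
                          sigma_pair = 0.25, sigma_ind = 0.20) {
  cv <- sd_hours / mean_hours
  cv_weibull <- function(k) sqrt(gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1)
  k <- stats::uniroot(function(k) cv_weibull(k) - cv, c(0.5, 200),
                      tol = 1e-12)$root
  beta0 <- -k * log(mean_hours / gamma(1 + 1 / k))
  weibull_frailty_params(
    shape = k, beta0 = beta0,
    beta = c("birth_cohort1900-1919" = log(1.11),
             "birth_cohort1920-1939" = log(1.41),
             "birth_cohort1940-1957" = log(1.62),
             "age_group35-54" = log(1.24),
             "age_group55+" = log(1.23),
             "gendermale" = log(1.13)),
    sigma_pair = sigma_pair, sigma_ind = sigma_ind)
}

#' Synthetic-cohort configuration
#'
#' Describes a simulated twin cohort with the structure of the four-wave
#' mailed survey: same-gender twin pairs sharing a birth year, wave-specific
#' birth-year eligibility and participation probabilities (the published
#' response rates 89/84/77/72 percent), wave-specific response schemes, and
#' latent durations from the Weibull frailty model.
#'
#' @param n_pairs Number of pairs.
#' @param frac_female Probability a pair is female.
#' @param birth_year_range Inclusive birth-year range, default 1880--1957
#'   (birth years are drawn uniformly; the real cohort's age pyramid is not
#'   reproduced).
#' @param waves Wave definitions as from [survey_waves()]; the
#'   `response_rate` column is used as the participation probability.
#' @param true_params Generating [weibull_frailty_params()].
#' @param frac_singleton Probability a "pair" has a single member,
#'   mirroring the non-twin individuals included in the first survey.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `"sleep_sim_config"`.
#' @export
sim_config <- function(n_pairs = 1000, frac_female = 0.54,
                       birth_year_range = c(1880L, 1957L),
                       waves = survey_waves(), true_params = default_truth(),
                       frac_singleton = 0, seed = 1L) {
  stopifnot(n_pairs >= 1, frac_female >= 0, frac_female <= 1,
            frac_singleton >= 0, frac_singleton <= 1,
            length(birth_year_range) == 2,
            birth_year_range[1] <= birth_year_range[2],
            all(waves$response_rate > 0), all(waves$response_rate <= 1),
            inherits(true_params, "weibull_frailty_params"))
  structure(list(n_pairs = as.integer(n_pairs), frac_female = frac_female,
                 birth_year_range = as.integer(birth_year_range),
                 waves = waves, true_params = true_params,
                 frac_singleton = frac_singleton, seed = as.integer(seed)),
            class = "sleep_sim_config")
}

# one RNG substream per pair keyed by (seed, pair index), so growing n_pairs
# leaves earlier pairs' draws unchanged; kept below 2^31
pair_seed <- function(seed, idx) {
  as.integer((abs(as.double(seed)) * 48271 + as.double(idx) * 104729) %%
               2147483629)
}

#' Simulate a twin-cohort survey dataset
#'
#' For each pair: draw a shared gender and birth year, a pair-level random
#' intercept, and per-subject individual intercepts; then for every wave in
#' which the pair is birth-year eligible and aged at least 18, include each
#' subject independently with the wave's participation probability, draw a
#' latent duration by inverse-CDF from the Weibull proportional-hazards
#' model at the subject's covariates plus both random intercepts, and record
#' the response category the wave's scheme assigns to that duration.
#' Fully reproducible from the seed, with one random substream per pair.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sleep_cohort_sim"` with `responses` (raw
#'   response tibble accepted by [as_sleep_responses()]), `latent`
#'   (per-observation truth record: random intercepts, linear predictor and
#'   latent duration), `truth` (the generating parameters) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sleep_sim_config"))
  tp <- config$true_params
  waves <- config$waves
  byr <- config$birth_year_range

  nW <- nrow(waves)
  # effect lookup tables (reference and absent levels contribute zero)
  eff <- function(levels, prefix) {
    v <- stats::setNames(numeric(length(levels)), levels)
    nm <- paste0(prefix, levels)
    hit <- nm %in% names(tp$beta)
    v[hit] <- tp$beta[nm[hit]]
    v
  }
  bc_eff <- eff(birth_cohort_levels, "birth_cohort")
  ag_eff <- eff(age_group_levels, "age_group")
  g_eff <- eff(gender_levels, "gender")

  acc <- vector("list", config$n_pairs)
  for (p in seq_len(config$n_pairs)) {
    set.seed(pair_seed(config$seed, p))
    n_members <- if (stats::runif(1) < config$frac_singleton) 1L else 2L
    gender <- if (stats::runif(1) < config$frac_female) "female" else "male"
    birth_year <- as.integer(stats::runif(1, byr[1], byr[2] + 1))
    u_pair <- stats::rnorm(1, 0, tp$sigma_pair)
    u_ind <- stats::rnorm(2, 0, tp$sigma_ind)[seq_len(n_members)]

    # fixed-length draw block per pair: (participation, latent) uniforms for
    # every member x wave, so the stream layout never depends on outcomes
    U <- matrix(stats::runif(2L * n_members * nW), nrow = 2L)
    jj <- rep(seq_len(n_members), each = nW)
    ww <- rep.int(seq_len(nW), n_members)
    eligible <- birth_year >= waves$birth_min & birth_year <= waves$birth_max &
      (waves$wave_year - birth_year) >= 18
    keep <- eligible[ww] & U[1L, ] <= waves$response_rate[ww]
    if (!any(keep)) next
    wy <- waves$wave_year[ww[keep]]
    age <- wy - birth_year
    ag <- age_group_levels[findInterval(age, c(18, 35, 55))]
    bc <- birth_cohort_levels[findInterval(birth_year,
                                           c(-Inf, 1900, 1920, 1940))]
    lp <- tp$beta0 + bc_eff[[bc]] + ag_eff[ag] + g_eff[[gender]] +
      u_pair + u_ind[jj[keep]]
    # inverse CDF: S(t) = exp(-t^k e^lp) = u  =>  t = (-log u / e^lp)^(1/k)
    t_lat <- (-log(U[2L, keep]) / exp(lp))^(1 / tp$shape)
    acc[[p]] <- list(p = p, j = jj[keep], wave_year = wy,
                     gender = gender, birth_year = birth_year,
                     u_pair = u_pair, u_ind = u_ind[jj[keep]],
                     linpred = lp, latent_t = t_lat)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  n_per <- vapply(acc, function(a) length(a$j), integer(1))
  col <- function(nm) unlist(lapply(acc, `[[`, nm), use.names = FALSE)
  rep_col <- function(nm) rep(vapply(acc, `[[`, vector(mode =
    if (nm == "gender") "character" else "numeric", 1), nm), n_per)
  p_v <- rep(vapply(acc, `[[`, integer(1), "p"), n_per)
  wy_v <- col("wave_year")
  t_v <- col("latent_t")
  cat_v <- character(length(t_v))
  sid_v <- scheme_for_wave(wy_v)
  for (s in unique(sid_v)) {
    idx <- sid_v == s
    cat_v[idx] <- discretize_duration(t_v[idx], s)
  }
  responses <- tibble::tibble(
    subject_id = sprintf("s%06d_%d", p_v, col("j")),
    pair_id = sprintf("p%06d", p_v),
    wave_year = as.integer(wy_v),
    gender = rep_col("gender"),
    birth_year = as.integer(rep_col("birth_year")),
    response_category = cat_v)
  latent <- tibble::tibble(
    subject_id = responses$subject_id, pair_id = responses$pair_id,
    wave_year = responses$wave_year,
    u_pair = rep_col("u_pair"), u_ind = col("u_ind"),
    linpred = col("linpred"), latent_t = t_v)
  structure(list(responses = responses, latent = latent,
                 truth = tp, config = config),
            class = "sleep_cohort_sim")
}

#' @export
print.sleep_cohort_sim <- function(x, ...) {
  cat("Synthetic twin-cohort survey:", nrow(x$responses), "responses from",
      dplyr::n_distinct(x$responses$subject_id), "subjects in",
      dplyr::n_distinct(x$responses$pair_id), "pairs (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the response CSV (via [write_responses()]) and a JSON truth record
#' holding the generating parameters and configuration.
#'
#' @param sim A `"sleep_cohort_sim"` object.
#' @param responses_path CSV path for the responses.
#' @param truth_path Optional JSON path for the truth record.
#' @return `responses_path`, invisibly.
#' @export
write_cohort_sim <- function(sim, responses_path, truth_path = NULL) {
  stopifnot(inherits(sim, "sleep_cohort_sim"))
  write_responses(sim$responses, responses_path)
  if (!is.null(truth_path)) {
    tp <- sim$truth
    obj <- list(
      params = list(shape = tp$shape, beta0 = tp$beta0,
                    beta = as.list(tp$beta), sigma_pair = tp$sigma_pair,
                    sigma_ind = tp$sigma_ind),
      config = list(n_pairs = sim$config$n_pairs,
                    frac_female = sim$config$frac_female,
                    birth_year_range = sim$config$birth_year_range,
                    frac_singleton = sim$config$frac_singleton,
                    seed = sim$config$seed),
      tool_version = as.character(utils::packageVersion("twinsleep")))
    jsonlite::write_json(obj, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(responses_path)
}
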