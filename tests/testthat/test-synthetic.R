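test_that("default truth encodes the published hazard ratios and calibrated reference mean", {
  tp <- default_truth()
  expect_equal(unname(exp(tp$beta)),
               c(1.11, 1.41, 1.62, 1.24, 1.23, 1.13))
  expect_equal(exp(tp$beta[["birth_cohort1940-1957"]]), 1.62)
  expect_equal(exp(tp$beta[["gendermale"]]), 1.13)
  mu <- mean_duration(tp)  # reference stratum, zero frailty
  expect_gt(mu, 7.5)
  expect_lt(mu, 7.9)
  # SD calibration
  sd_ref <- sqrt(gamma(1 + 2 / tp$shape) - gamma(1 + 1 / tp$shape)^2) *
    exp(-tp$beta0 / tp$shape)
  expect_equal(sd_ref, 0.9, tolerance = 1e-8)
})

test_that("simulation is reproducible and earlier pairs are stable as the cohort grows", {
  cfg <- sim_config(n_pairs = 100, seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$latent, s2$latent)

  big <- simulate_cohort(sim_config(n_pairs = 150, seed = 42))
  first100 <- big$responses[big$responses$pair_id %in%
                              unique(s1$responses$pair_id), ]
  expect_identical(as.data.frame(first100), as.data.frame(s1$responses))
})

test_that("wave eligibility windows are respected", {
  sim <- simulate_cohort(sim_config(n_pairs = 600, seed = 3))
  r <- sim$responses
  expect_true(all(r$birth_year[r$wave_year == 1990] >= 1930))
  expect_true(all(r$birth_year[r$wave_year == 2011] >= 1945))
  expect_true(all(r$birth_year <= 1957))
  expect_true(all(r$wave_year - r$birth_year >= 18))
  # twins share gender and birth year; pairs have at most two members
  per_pair <- dplyr::summarise(
    dplyr::group_by(r, pair_id),
    ns = dplyr::n_distinct(subject_id), ng = dplyr::n_distinct(gender),
    nb = dplyr::n_distinct(birth_year), .groups = "drop")
  expect_true(all(per_pair$ns <= 2))
  expect_true(all(per_pair$ng == 1))
  expect_true(all(per_pair$nb == 1))
})

test_that("participation tracks the configured response rates", {
  cfg <- sim_config(n_pairs = 1500, seed = 8)
  sim <- simulate_cohort(cfg)
  r <- sim$responses
  waves <- cfg$waves
  # count eligible subject-waves from the drawn pairs
  subjects <- dplyr::distinct(r, subject_id, birth_year)
  for (w in seq_len(nrow(waves))) {
    elig <- subjects$birth_year >= waves$birth_min[w] &
      subjects$birth_year <= waves$birth_max[w] &
      (waves$wave_year[w] - subjects$birth_year) >= 18
    n_elig <- sum(elig)
    n_obs <- sum(r$wave_year == waves$wave_year[w])
    p <- waves$response_rate[w]
    se <- sqrt(p * (1 - p) / n_elig)
    expect_lt(abs(n_obs / n_elig - p), 3 * se + 0.01)
  }
})

test_that("null-model latent durations follow the baseline Weibull", {
  tp0 <- weibull_frailty_params(shape = default_truth()$shape,
                                beta0 = default_truth()$beta0)
  sim <- simulate_cohort(sim_config(n_pairs = 2600, seed = 12,
                                    true_params = tp0))
  t_lat <- sim$latent$latent_t[!duplicated(paste(sim$latent$subject_id,
                                                 sim$latent$wave_year))]
  t_lat <- utils::head(t_lat, 10000)
  ks <- stats::ks.test(t_lat, function(q) {
    1 - weibull_ph_survival(q, tp0$beta0, tp0$shape)
  })
  expect_gt(ks$p.value, 0.01)
})

test_that("discretization of simulated durations is consistent with the schemes", {
  sim <- simulate_cohort(sim_config(n_pairs = 150, seed = 55))
  r <- sim$responses
  lat <- sim$latent
  sid <- scheme_for_wave(r$wave_year)
  for (s in unique(sid)) {
    idx <- sid == s
    m <- map_response(r$response_category[idx], s)
    expect_true(all(lat$latent_t[idx] >= m$left & lat$latent_t[idx] < m$right))
  }
})

test_that("singleton fraction produces size-1 pairs", {
  sim <- simulate_cohort(sim_config(n_pairs = 300, seed = 9,
                                    frac_singleton = 0.5))
  sizes <- dplyr::summarise(
    dplyr::group_by(sim$responses, pair_id),
    ns = dplyr::n_distinct(subject_id), .groups = "drop")
  expect_true(any(sizes$ns == 1))
  expect_true(any(sizes$ns == 2))
  d <- as_sleep_responses(sim$responses)  # still validates
  expect_s3_class(d, "tbl_df")
})

test_that("truth record serializes alongside the responses", {
  sim <- simulate_cohort(sim_config(n_pairs = 20, seed = 77))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cohort_sim(sim, csv, js)
  d <- read_responses(csv)
  expect_equal(nrow(d), nrow(sim$responses))
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(truth$params$shape, sim$truth$shape)
  expect_equal(truth$config$seed, 77)
})
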