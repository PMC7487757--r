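# Independent oracles and small fixture builders used across the suite.

# Fixed-effects interval-censored Weibull log-likelihood via stats::pweibull,
# independent of the package's survival parameterisation:
# S(t) = exp(-t^k e^lp) corresponds to pweibull scale exp(-lp/k).
fe_loglik_pweibull <- function(left, right, lp, shape) {
  sc <- exp(-lp / shape)
  p <- stats::pweibull(left, shape, sc, lower.tail = FALSE) -
    ifelse(is.finite(right),
           stats::pweibull(right, shape, sc, lower.tail = FALSE), 0)
  sum(log(p))
}

# linear predictor for enriched data under truth parameters, via model.matrix
# (mirrors the published factor coding, not the package's internal builder)
oracle_linpred <- function(data, params) {
  df <- data.frame(
    birth_cohort = factor(data$birth_cohort,
                          c("<1900", "1900-1919", "1920-1939", "1940-1957")),
    age_group = factor(data$age_group, c("18-34", "35-54", "55+")),
    gender = factor(data$gender, c("female", "male")))
  X <- stats::model.matrix(~ birth_cohort + age_group + gender, df)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  drop(params$beta0 + X %*% params$beta[colnames(X)])
}

# Monte Carlo estimate of the nested-frailty marginal log-likelihood with a
# delta-method standard error; independent of the quadrature code path.
mc_marginal_loglik <- function(data, params, n_draws = 2e5, seed = 1) {
  set.seed(seed)
  data$lp <- oracle_linpred(data, params)
  total <- 0
  var_total <- 0
  for (pair in split(data, data$pair_id)) {
    u_pair <- stats::rnorm(n_draws, 0, params$sigma_pair)
    Lr <- rep(1, n_draws)
    for (subj in split(pair, pair$subject_id)) {
      u_ind <- stats::rnorm(n_draws, 0, params$sigma_ind)
      for (i in seq_len(nrow(subj))) {
        eta <- subj$lp[i] + u_pair + u_ind
        sc <- exp(-eta / params$shape)
        Pi <- stats::pweibull(subj$left[i], params$shape, sc,
                              lower.tail = FALSE)
        if (is.finite(subj$right[i])) {
          Pi <- Pi - stats::pweibull(subj$right[i], params$shape, sc,
                                     lower.tail = FALSE)
        }
        Lr <- Lr * Pi
      }
    }
    Lhat <- mean(Lr)
    se <- stats::sd(Lr) / sqrt(n_draws)
    total <- total + log(Lhat)
    var_total <- var_total + (se / Lhat)^2
  }
  list(loglik = total, se = sqrt(var_total))
}

# small enriched dataset with controllable size
toy_cohort <- function(n_pairs = 8, seed = 11,
                       truth = default_truth(sigma_pair = 0.3,
                                             sigma_ind = 0.2)) {
  sim <- simulate_cohort(sim_config(n_pairs = n_pairs, seed = seed,
                                    true_params = truth))
  as_sleep_responses(sim$responses)
}

# hand-buildable raw response table
raw_rows <- function(...) {
  tibble::tribble(
    ~subject_id, ~pair_id, ~wave_year, ~gender, ~birth_year,
    ~response_category, ...)
}
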