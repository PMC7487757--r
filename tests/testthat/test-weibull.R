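test_that("survival function matches closed forms and a quadrature oracle", {
  expect_equal(weibull_ph_survival(1, 0, 1), exp(-1))
  expect_equal(weibull_ph_survival(0, 3.2, 5.5), 1)
  expect_equal(weibull_ph_survival(Inf, 0, 2), 0)
  # S(t) equals the integral of the density from t to infinity
  dens <- function(x, lp, k) k * x^(k - 1) * exp(lp) * exp(-x^k * exp(lp))
  s_num <- stats::integrate(dens, 7.5, Inf, lp = -15, k = 7,
                            rel.tol = 1e-12)$value
  expect_equal(weibull_ph_survival(7.5, -15, 7), s_num, tolerance = 1e-8)
  expect_error(weibull_ph_survival(-1, 0, 1), "t >= 0")
  expect_error(weibull_ph_survival(1, 0, -2), "shape > 0")
})

test_that("conditional interval log-likelihood matches density integration", {
  expect_equal(interval_loglik(0, Inf, 2.3, 4.1), 0)
  # exponential special case: right-censoring at L with unit hazard
  expect_equal(interval_loglik(3.7, Inf, 0, 1), -3.7)
  dens <- function(x, lp, k) k * x^(k - 1) * exp(lp) * exp(-x^k * exp(lp))
  p_num <- stats::integrate(dens, 6.75, 7.25, lp = -13.4, k = 6.8,
                            rel.tol = 1e-12)$value
  expect_equal(interval_loglik(6.75, 7.25, -13.4, 6.8), log(p_num),
               tolerance = 1e-8)
  # underflowing interval signals -Inf
  expect_identical(interval_loglik(20, 20.5, 10, 8), -Inf)
})

test_that("marginal likelihood collapses to the fixed-effects likelihood and a single whole-support interval gives zero", {
  d <- toy_cohort(n_pairs = 12, seed = 21)
  params <- default_truth(sigma_pair = 0, sigma_ind = 0)
  ll <- marginal_loglik(d, params, quad_order = 25)
  ref <- fe_loglik_pweibull(d$left, d$right, oracle_linpred(d, params),
                            params$shape)
  expect_equal(ll, ref, tolerance = 1e-12)

  whole <- raw_rows("a", "p", 1975, "male", 1940, "7")
  whole <- as_sleep_responses(whole)
  whole$left <- 0
  whole$right <- Inf
  expect_equal(marginal_loglik(whole, default_truth(), 15), 0,
               tolerance = 1e-12)
})

test_that("nested quadrature agrees with a Monte Carlo oracle", {
  d <- toy_cohort(n_pairs = 6, seed = 31)
  params <- default_truth(sigma_pair = 0.3, sigma_ind = 0.2)
  gh <- marginal_loglik(d, params, quad_order = 25)
  mc <- mc_marginal_loglik(d, params, n_draws = 2e5, seed = 99)
  expect_lt(abs(gh - mc$loglik), 3 * mc$se)
})

test_that("time-unit change with compensated intercept leaves the likelihood invariant", {
  # hours -> minutes: t' = 60 t, k unchanged, beta0' = beta0 - k log 60
  d <- toy_cohort(n_pairs = 10, seed = 41)
  p1 <- default_truth(sigma_pair = 0.25, sigma_ind = 0.2)
  d2 <- d
  d2$left <- d$left * 60
  d2$right <- d$right * 60
  p2 <- p1
  p2$beta0 <- p1$beta0 - p1$shape * log(60)
  expect_equal(marginal_loglik(d, p1, 20), marginal_loglik(d2, p2, 20),
               tolerance = 1e-10)
})

test_that("with sigma_ind = 0 the nested likelihood equals a one-level pair-frailty computation", {
  d <- toy_cohort(n_pairs = 8, seed = 51)
  d <- d[d$wave_year == 1975, ]
  params <- default_truth(sigma_pair = 0.35, sigma_ind = 0)
  nested <- marginal_loglik(d, params, quad_order = 25)
  # independent single-level Gauss-Hermite over the pair intercept
  gh <- pracma::gaussHermite(25)
  w <- gh$w / sum(gh$w)
  u <- sqrt(2) * params$sigma_pair * gh$x
  lp <- oracle_linpred(d, params)
  one_level <- sum(vapply(split(seq_len(nrow(d)), d$pair_id), function(idx) {
    contrib <- vapply(seq_along(u), function(q) {
      sc <- exp(-(lp[idx] + u[q]) / params$shape)
      p <- stats::pweibull(d$left[idx], params$shape, sc,
                           lower.tail = FALSE) -
        ifelse(is.finite(d$right[idx]),
               stats::pweibull(d$right[idx], params$shape, sc,
                               lower.tail = FALSE), 0)
      prod(p)
    }, numeric(1))
    log(sum(w * contrib))
  }, numeric(1)))
  expect_equal(nested, one_level, tolerance = 1e-6)
})

test_that("mean duration has the Weibull closed form and integrates S(t)", {
  expect_equal(mean_duration(weibull_frailty_params(1, 0)), 1)
  expect_equal(mean_duration(weibull_frailty_params(2, 0)), gamma(1.5))
  p <- default_truth()
  mu <- mean_duration(p, list(gender = "male", age_group = "55+"))
  lp <- p$beta0 + p$beta[["gendermale"]] + p$beta[["age_group55+"]]
  mu_num <- stats::integrate(function(t) weibull_ph_survival(t, lp, p$shape),
                             0, Inf, rel.tol = 1e-10)$value
  expect_equal(mu, mu_num, tolerance = 1e-6)
})

test_that("raising any hazard coefficient weakly shortens implied mean sleep", {
  p <- default_truth()
  base <- mean_duration(p)
  for (term in names(p$beta)) {
    expect_true(p$beta[[term]] > 0)  # all published HRs exceed 1
  }
  # shorter-sleep direction: each non-reference level has smaller mean
  expect_lt(mean_duration(p, list(gender = "male")), base)
  expect_lt(mean_duration(p, list(birth_cohort = "1940-1957")),
            mean_duration(p, list(birth_cohort = "1900-1919")))
})

test_that("hazard_ratios reproduces Wald arithmetic and reference rows", {
  d <- toy_cohort(n_pairs = 150, seed = 61)
  fit <- suppressWarnings(fit_weibull_frailty(d, quad_order = 9,
                                              frailty = "none"))
  hr <- hazard_ratios(fit, level = 0.95)
  expect_equal(sum(hr$is_reference), 3)
  expect_equal(hr$hr[hr$is_reference], rep(1, 3))
  expect_true(all(is.na(hr$ci_low[hr$is_reference])))
  est <- hr[!hr$is_reference, ]
  expect_true(all(est$ci_low <= est$hr & est$hr <= est$ci_high))
  # closed-form check against the internal covariance
  z <- stats::qnorm(0.975)
  for (i in seq_len(nrow(est))) {
    b <- fit$params$beta[[est$term[i]]]
    se <- sqrt(fit$vcov[est$term[i], est$term[i]])
    expect_equal(est$hr[i], exp(b))
    expect_equal(est$ci_low[i], exp(b - z * se))
    expect_equal(est$ci_high[i], exp(b + z * se))
  }
  # worked Wald example: beta = log 1.62, se = 0.0765 -> CI about (1.40, 1.88)
  expect_equal(exp(log(1.62) - z * 0.0765), 1.395, tolerance = 1e-3)
  expect_equal(exp(log(1.62) + z * 0.0765), 1.882, tolerance = 1e-3)
})

test_that("predicted survival curves are proper and match a Monte Carlo frailty average", {
  p <- default_truth(sigma_pair = 0.4, sigma_ind = 0.3)
  tg <- seq(0, 12, by = 0.5)
  z <- predict_survival(p, list(gender = "male"), tg, frailty = "zero")
  expect_equal(z$surv[1], 1)
  expect_true(all(diff(z$surv) <= 1e-12))

  p0 <- default_truth(sigma_pair = 0, sigma_ind = 0)
  m0 <- predict_survival(p0, list(), tg, frailty = "marginal")
  z0 <- predict_survival(p0, list(), tg, frailty = "zero")
  expect_equal(m0$surv, z0$surv, tolerance = 1e-12)

  m <- predict_survival(p, list(gender = "male"), tg, frailty = "marginal")
  set.seed(71)
  n_mc <- 1e5
  u <- stats::rnorm(n_mc, 0, sqrt(p$sigma_pair^2 + p$sigma_ind^2))
  lp <- p$beta0 + p$beta[["gendermale"]]
  mc <- vapply(tg, function(t) mean(exp(-t^p$shape * exp(lp + u))),
               numeric(1))
  mc_se <- vapply(tg, function(t) {
    stats::sd(exp(-t^p$shape * exp(lp + u))) / sqrt(n_mc)
  }, numeric(1))
  expect_true(all(abs(m$surv - mc) < 3 * mc_se + 1e-12))
  expect_error(predict_survival(p, list(age_group = "80+"), tg), "unknown")
})

test_that("fit recovers structure on a moderate cohort and is quadrature-stable", {
  d <- toy_cohort(n_pairs = 300, seed = 81)
  f15 <- fit_weibull_frailty(d, quad_order = 15)
  expect_true(f15$converged)
  expect_equal(f15$n_obs, nrow(d))
  expect_equal(f15$n_pairs, length(unique(d$pair_id)))
  # covariance is symmetric positive definite on convergence
  expect_equal(f15$vcov, t(f15$vcov), tolerance = 1e-6)
  expect_true(all(eigen(f15$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  f35 <- fit_weibull_frailty(d, quad_order = 35)
  expect_lt(max(abs(f15$theta - f35$theta)), 1e-3)
})

test_that("degenerate one-category data is flagged, not a crash", {
  raw <- raw_rows(
    "a1", "p1", 1981, "male", 1940, "10 h or more",
    "a2", "p1", 1981, "male", 1940, "10 h or more",
    "b1", "p2", 1981, "male", 1940, "10 h or more",
    "b2", "p2", 1981, "male", 1940, "10 h or more")
  d <- as_sleep_responses(raw)
  fit <- suppressWarnings(fit_weibull_frailty(d, quad_order = 7,
                                              frailty = "none",
                                              max_iter = 50))
  expect_false(fit$converged)
  expect_match(fit$status, "converge|Hessian|diverged|boundary",
               ignore.case = TRUE)
})

test_that("tidy and glance expose broom-style summaries", {
  d <- toy_cohort(n_pairs = 120, seed = 91)
  fit <- suppressWarnings(fit_weibull_frailty(d, quad_order = 9))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "statistic",
                    "p.value", "conf.low", "conf.high") %in% names(td)))
  expect_equal(nrow(td), length(fit$theta))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(d))
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(gl$AIC, 2 * length(fit$theta) - 2 * fit$loglik)
  pl <- autoplot(fit)
  expect_s3_class(pl, "ggplot")
})
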