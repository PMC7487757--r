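test_that("innermost sets are the maximal intersections", {
  s <- turnbull_sets(c(1, 1), c(2, 2))
  expect_equal(as.data.frame(s), data.frame(left = 1, right = 2))

  s <- turnbull_sets(c(0, 1), c(2, 3))
  expect_equal(as.data.frame(s), data.frame(left = 1, right = 2))

  s <- turnbull_sets(6.25, 6.75)
  expect_equal(as.data.frame(s), data.frame(left = 6.25, right = 6.75))

  # disjoint intervals keep both sets; an enclosing interval adds none
  s <- turnbull_sets(c(0, 2, 0), c(1, 3, 5))
  expect_equal(as.data.frame(s), data.frame(left = c(0, 2), right = c(1, 3)))
})

test_that("NPMLE on effectively uncensored data equals the empirical survival function", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  eps <- 1e-6
  est <- npmle(x - eps, x + eps)
  expect_true(est$converged)
  expect_equal(sum(est$sets$mass), 1, tolerance = 1e-10)
  # survival at each drop time equals 1 - ecdf
  surv_emp <- 1 - stats::ecdf(x)(sort(unique(x)))
  drops <- est$curve$surv[-1]
  expect_equal(drops, surv_emp, tolerance = 1e-6)
})

test_that("EM log-likelihood is nondecreasing and masses are conserved", {
  set.seed(17)
  d <- toy_cohort(n_pairs = 60, seed = 17)
  est <- npmle(d$left, d$right)
  expect_true(est$converged)
  expect_equal(sum(est$sets$mass), 1, tolerance = 1e-10)
  expect_true(all(diff(est$loglik_path) > -1e-9))
  expect_true(all(diff(est$curve$surv) <= 1e-12))
  expect_equal(est$curve$surv[1], 1)
})

test_that("two half-overlapping intervals match a one-parameter grid-search oracle", {
  # observations [0,2) and [1,3): innermost sets [1,2) within both;
  # candidate masses m on [1,2) vs on the outer parts
  est <- npmle(c(0, 1), c(2, 3))
  # direct likelihood: all mass configurations live on [1,2) only here
  expect_equal(nrow(est$sets), 1)
  expect_equal(est$sets$mass, 1, tolerance = 1e-10)

  # a genuinely two-set case: [0,1.5) and [1,3) give sets [1,1.5) shared
  # and none other... use three observations to force a trade-off
  l <- c(0, 0, 1.2)
  r <- c(1, 1.5, 3)
  sets <- turnbull_sets(l, r)
  est <- npmle(l, r)
  # grid search over the simplex of the same innermost sets
  A <- outer(l, sets$left, `<=`) & outer(r, sets$right, `>=`)
  grid <- seq(0, 1, by = 1e-4)
  best <- -Inf
  best_m <- NULL
  for (m1 in grid) {
    m <- c(m1, 1 - m1)
    ll <- sum(log(drop(A %*% m)))
    if (ll > best) {
      best <- ll
      best_m <- m
    }
  }
  expect_equal(est$sets$mass, best_m, tolerance = 1e-3)
  expect_gte(est$loglik, best - 1e-6)
})

test_that("NPMLE agrees with the survival package's Turnbull estimate", {
  d <- toy_cohort(n_pairs = 80, seed = 23)
  d <- d[d$wave_year == 1981, ]
  est <- npmle(d$left, d$right)
  sf <- survival::survfit(
    survival::Surv(d$left, ifelse(is.finite(d$right), d$right, NA),
                   type = "interval2") ~ 1)
  # compare survival just past each finite innermost right endpoint
  fin <- is.finite(est$sets$right)
  s_mine <- 1 - cumsum(est$sets$mass)[fin]
  s_pkg <- vapply(est$sets$right[fin], function(t) {
    min(sf$surv[sf$time <= t + 1e-9])
  }, numeric(1))
  expect_equal(unname(s_mine), unname(s_pkg), tolerance = 1e-4)
})

test_that("midpoint Kaplan-Meier reduces to the textbook product-limit estimator", {
  # no censoring: steps of 1/3
  km <- km_midpoint(c(0.9, 1.9, 2.9), c(1.1, 2.1, 3.1))
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 0))

  # all right-censored: flat at 1
  km <- km_midpoint(c(5, 6, 7), c(Inf, Inf, Inf))
  expect_true(all(km$surv == 1))

  # mixed hand-computed table: events at 1, 3 and censorings at 2, 4
  # risk sets: t=1 n=4 d=1 -> 3/4; t=3 n=2 d=1 -> 3/8 (flat at censor times)
  km <- km_midpoint(c(0.5, 2, 2.5, 4), c(1.5, Inf, 3.5, Inf))
  expect_equal(km$time, c(0, 1, 2, 3, 4))
  expect_equal(km$surv, c(1, 0.75, 0.75, 0.375, 0.375))
})

test_that("on unambiguous data NPMLE and midpoint KM coincide at support points", {
  # disjoint narrow intervals: no overlap ambiguity
  l <- c(1, 1, 3, 5, 5, 5)
  r <- l + 0.2
  np <- npmle(l, r)
  km <- km_midpoint(l, r)
  # survival after each interval
  np_s <- np$curve$surv[-1]
  km_s <- vapply(r, function(t) min(km$surv[km$time <= t]), numeric(1))
  expect_equal(np_s, unique(km_s), tolerance = 1e-8)
})

test_that("grouped survival curves return tidy long output and plot", {
  d <- toy_cohort(n_pairs = 50, seed = 29)
  cv <- survival_curves(d, by = "wave_year", method = "turnbull")
  expect_true(all(c("group", "time", "surv") %in% names(cv)))
  expect_setequal(unique(cv$group), as.character(unique(d$wave_year)))
  for (g in unique(cv$group)) {
    s <- cv$surv[cv$group == g]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
  }
  pl <- autoplot(cv)
  expect_s3_class(pl, "ggplot")
})
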