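#' Weibull proportional-hazards survival function
#'
#' The latent sleep duration follows a Weibull proportional-hazards model
#' with hazard \eqn{h(t) = k t^{k-1} e^{\eta}}, so
#' \eqn{S(t) = \exp(-t^k e^{\eta})} where \eqn{\eta} is the linear predictor
#' on the log-hazard scale. A hazard ratio above 1 means a higher rate of the
#' latent duration ending, i.e. shorter sleep.
#'
#' @param t Durations in hours (\eqn{t \ge 0}; `Inf` allowed, giving 0).
#' @param linpred Linear predictor \eqn{\eta} (log relative hazard).
#' @param shape Weibull shape \eqn{k > 0}.
#' @return Survival probabilities, same length as the longest argument.
#' @examples
#' weibull_ph_survival(1, 0, 1)   # exp(-1)
#' @export
weibull_ph_survival <- function(t, linpred = 0, shape = 1) {
  if (any(!is.finite(linpred)) || any(!is.finite(shape)) || any(shape <= 0) ||
      any(is.na(t)) || any(t < 0)) {
    stop("require t >= 0, finite linpred, shape > 0", call. = FALSE)
  }
  n <- max(length(t), length(linpred), length(shape))
  t <- rep_len(t, n)
  out <- exp(-t^rep_len(shape, n) * exp(rep_len(linpred, n)))
  out[is.infinite(t)] <- 0
  out
}

#' Conditional log-likelihood of one censoring interval
#'
#' Log probability that the latent duration falls in `[left, right)` given
#' the linear predictor: `log(S(left) - S(right))`, with `S(0) = 1` and
#' `S(Inf) = 0`. Returns `-Inf` when the interval probability underflows;
#' the marginal-likelihood evaluator substitutes a large finite penalty
#' instead so optimisation line searches stay stable.
#'
#' @param left,right Interval bounds in hours (`right` may be `Inf`).
#' @inheritParams weibull_ph_survival
#' @return Log-probabilities, always \eqn{\le 0}.
#' @export
interval_loglik <- function(left, right, linpred = 0, shape = 1) {
  if (any(right <= left)) stop("require left < right", call. = FALSE)
  p <- weibull_ph_survival(left, linpred, shape) -
    weibull_ph_survival(right, linpred, shape)
  ifelse(p > 0, log(p), -Inf)
}

#' Parameters of the Weibull frailty model
#'
#' Bundles the shape, the intercept and regression coefficients on the
#' log-hazard scale, and the standard deviations of the two mean-zero normal
#' random intercepts: one shared within a twin pair, one per individual
#' (constant across that individual's repeated surveys), nested pair over
#' individual. `exp(beta)` are hazard ratios for shorter sleep. Reference
#' levels (birth cohort <1900, age 18--34, female) carry no coefficient.
#'
#' @param shape Weibull shape \eqn{k > 0}.
#' @param beta0 Intercept of the log-hazard scale.
#' @param beta Named numeric vector of log hazard ratios; names follow
#'   `model.matrix` conventions, e.g. `"birth_cohort1940-1957"`,
#'   `"age_group55+"`, `"gendermale"`.
#' @param sigma_pair,sigma_ind Frailty standard deviations, \eqn{\ge 0}.
#' @return An object of class `"weibull_frailty_params"`.
#' @export
weibull_frailty_params <- function(shape, beta0, beta = numeric(0),
                                   sigma_pair = 0, sigma_ind = 0) {
  stopifnot(is.numeric(shape), length(shape) == 1, shape > 0,
            is.numeric(beta0), length(beta0) == 1,
            sigma_pair >= 0, sigma_ind >= 0)
  if (length(beta) && is.null(names(beta))) {
    stop("beta must be a named vector", call. = FALSE)
  }
  structure(list(shape = shape, beta0 = beta0, beta = beta,
                 sigma_pair = sigma_pair, sigma_ind = sigma_ind),
            class = "weibull_frailty_params")
}

#' @export
print.weibull_frailty_params <- function(x, ...) {
  cat("Weibull frailty parameters\n")
  cat("  shape k:", format(x$shape, digits = 4),
      " intercept:", format(x$beta0, digits = 4), "\n")
  if (length(x$beta)) {
    cat("  hazard ratios:\n")
    print(round(exp(x$beta), 3))
  }
  cat("  sigma_pair:", x$sigma_pair, " sigma_ind:", x$sigma_ind, "\n")
  invisible(x)
}

# linear predictor beta0 + x'beta for enriched response data; every design
# column must have a coefficient, extra coefficients are allowed (levels
# absent from the data)
linpred_fixed <- function(data, params) {
  X <- design_matrix(data)
  if (ncol(X)) {
    miss <- setdiff(colnames(X), names(params$beta))
    if (length(miss)) {
      stop("no coefficient for design column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    drop(params$beta0 + X %*% params$beta[colnames(X)])
  } else {
    rep(params$beta0, nrow(data))
  }
}

design_matrix <- function(data) {
  df <- data.frame(
    birth_cohort = factor(data$birth_cohort, birth_cohort_levels),
    age_group = factor(data$age_group, age_group_levels),
    gender = factor(data$gender, gender_levels))
  X <- stats::model.matrix(~ birth_cohort + age_group + gender, df)
  X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
}

# CSR-style grouping of observations by pair and subject; rows are reordered
# so each subject, then each pair, is contiguous
group_structure <- function(data) {
  ord <- order(data$pair_id, data$subject_id)
  data <- data[ord, , drop = FALSE]
  subj_key <- paste(data$pair_id, data$subject_id, sep = "\r")
  subj_rle <- rle(subj_key)
  subj_ptr <- c(0L, cumsum(subj_rle$lengths))
  pair_of_subj <- data$pair_id[subj_ptr[-length(subj_ptr)] + 1L]
  pair_rle <- rle(pair_of_subj)
  pair_ptr <- c(0L, cumsum(pair_rle$lengths))
  list(data = data, subj_ptr = as.integer(subj_ptr),
       pair_ptr = as.integer(pair_ptr),
       n_subjects = length(subj_rle$lengths),
       n_pairs = length(pair_rle$lengths))
}

gh_rule <- function(n) {
  r <- pracma::gaussHermite(n)
  list(x = r$x, w = r$w)
}

#' Marginal log-likelihood under nested frailty
#'
#' Integrates the conditional interval-censored Weibull likelihood over the
#' pair-level and individual-level normal random intercepts by nested
#' Gauss--Hermite quadrature: for each pair,
#' \deqn{\log \int \phi(u_p)\prod_j \int \phi(u_j) \prod_i P_i(\eta_i + u_p + u_j)\, du_j\, du_p.}
#' With `sigma_pair = sigma_ind = 0` it reduces exactly to the fixed-effects
#' interval-censored log-likelihood.
#'
#' @param data Enriched response tibble (see [as_sleep_responses()]).
#' @param params A [weibull_frailty_params()] object.
#' @param quad_order Gauss--Hermite nodes per level (\eqn{\ge 3}).
#' @return The marginal log-likelihood (a single number).
#' @export
marginal_loglik <- function(data, params, quad_order = 25) {
  stopifnot(inherits(params, "weibull_frailty_params"), quad_order >= 3)
  if (nrow(data) == 0L) stop("empty data", call. = FALSE)
  gs <- group_structure(data)
  lp <- linpred_fixed(gs$data, params)
  gh <- gh_rule(quad_order)
  cpp_marginal_loglik(gs$data$left, gs$data$right, lp, gs$subj_ptr,
                      gs$pair_ptr, params$shape, params$sigma_pair,
                      params$sigma_ind, gh$x, gh$w, gh$x, gh$w)
}

# censoring-ignorant moment initialisation: match mean/CV of midpoint-coded
# durations to a Weibull with u = 0
moment_init <- function(data) {
  mid <- (data$left + ifelse(is.finite(data$right), data$right,
                             data$left + 0.5)) / 2
  mid[data$left == 0] <- data$right[data$left == 0] - 0.25
  mu <- mean(mid)
  cv <- stats::sd(mid) / mu
  cv_weibull <- function(k) {
    sqrt(gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1)
  }
  k0 <- tryCatch(
    stats::uniroot(function(k) cv_weibull(k) - cv, c(0.5, 150))$root,
    error = function(e) 2)
  beta00 <- -k0 * log(mu / gamma(1 + 1 / k0))
  list(shape = k0, beta0 = beta00)
}

#' Fit the interval-censored Weibull model with nested frailty
#'
#' Maximum-likelihood estimation on the unconstrained scale
#' (`log shape`, `beta0`, `beta`, `log sigma`) by quasi-Newton (BFGS)
#' optimisation of the nested Gauss--Hermite marginal likelihood. The
#' covariates are the three study factors: birth cohort (reference <1900),
#' age group (reference 18--34) and gender (reference female). Factor levels
#' absent from the data are dropped with a warning; an exactly rank-deficient
#' design is an error. The covariance of the estimates comes from the inverse
#' numerical Hessian at the optimum. The fit is deterministic given the data,
#' initial values and settings.
#'
#' @param data Enriched response tibble (see [as_sleep_responses()]).
#' @param quad_order Gauss--Hermite nodes per frailty level.
#' @param frailty Which random intercepts to estimate: `"nested"` (pair and
#'   individual), `"pair"`, `"individual"`, or `"none"` (fixed effects only).
#' @param init Optional [weibull_frailty_params()] start values; defaults to
#'   a censoring-ignorant moment fit for shape and intercept, zero
#'   coefficients and frailty SDs of 0.1.
#' @param tol Relative convergence tolerance passed to the optimiser.
#' @param max_iter Iteration cap.
#' @return An object of class `"sleep_weibull_fit"` with elements `params`
#'   (the estimates as [weibull_frailty_params()]), `loglik`, `vcov` (on the
#'   unconstrained internal scale, row/col names matching `theta`), `theta`
#'   (the internal parameter vector), `converged`, `status`, counts, and the
#'   settings used. Non-convergence is flagged, never silent.
#' @export
fit_weibull_frailty <- function(data, quad_order = 25,
                                frailty = c("nested", "pair", "individual",
                                            "none"),
                                init = NULL, tol = 1e-8, max_iter = 500) {
  frailty <- match.arg(frailty)
  if (nrow(data) == 0L) stop("empty data", call. = FALSE)

  # drop unused factor levels (references re-anchor to the first level left)
  facs <- list(birth_cohort = birth_cohort_levels,
               age_group = age_group_levels, gender = gender_levels)
  df <- data
  used_levels <- list()
  for (f in names(facs)) {
    fac <- factor(as.character(df[[f]]), facs[[f]])
    fac <- droplevels(fac)
    dropped <- setdiff(facs[[f]], levels(fac))
    if (length(dropped)) {
      warning("dropping absent ", f, " level(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    used_levels[[f]] <- levels(fac)
    df[[f]] <- fac
  }
  mm_df <- data.frame(lapply(df[names(facs)], identity))
  # factors collapsing to a single level contribute no columns
  active <- names(facs)[vapply(mm_df, nlevels, 1L) > 1L]
  build_X <- function(d) {
    if (!length(active)) return(matrix(0, nrow(d), 0))
    M <- stats::model.matrix(stats::reformulate(active), d)
    M[, setdiff(colnames(M), "(Intercept)"), drop = FALSE]
  }
  X <- build_X(mm_df)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("design matrix is rank deficient; drop a confounded factor",
         call. = FALSE)
  }
  coef_names <- colnames(X)

  gs <- group_structure(df)
  # group_structure reorders rows; rebuild the design in that order
  Xo <- build_X(as.data.frame(gs$data[names(facs)]))[, coef_names,
                                                     drop = FALSE]

  m0 <- moment_init(gs$data)
  if (is.null(init)) {
    init <- weibull_frailty_params(
      shape = m0$shape, beta0 = m0$beta0,
      beta = stats::setNames(rep(0, length(coef_names)), coef_names),
      sigma_pair = if (frailty %in% c("nested", "pair")) 0.1 else 0,
      sigma_ind = if (frailty %in% c("nested", "individual")) 0.1 else 0)
  }
  est_sp <- frailty %in% c("nested", "pair")
  est_si <- frailty %in% c("nested", "individual")

  theta0 <- c(log_shape = log(init$shape), beta0 = init$beta0,
              stats::setNames(
                if (length(coef_names)) {
                  b <- rep(0, length(coef_names))
                  b[match(names(init$beta), coef_names)] <-
                    init$beta[names(init$beta) %in% coef_names]
                  b
                } else numeric(0), coef_names),
              if (est_sp) c(log_sigma_pair = log(max(init$sigma_pair, 1e-3))),
              if (est_si) c(log_sigma_ind = log(max(init$sigma_ind, 1e-3))))

  gh <- gh_rule(quad_order)
  nb <- length(coef_names)
  unpack <- function(theta) {
    list(shape = exp(theta[1]), beta0 = theta[2],
         beta = if (nb) theta[2 + seq_len(nb)] else numeric(0),
         sigma_pair = if (est_sp) exp(theta[2 + nb + 1]) else 0,
         sigma_ind = if (est_si) exp(theta[2 + nb + 1 + est_sp]) else 0)
  }
  eval_ll <- function(theta, want_grad) {
    p <- unpack(theta)
    lp <- p$beta0 + if (nb) drop(Xo %*% p$beta) else 0
    cpp_marginal_loglik_grad(gs$data$left, gs$data$right, lp, gs$subj_ptr,
                             gs$pair_ptr, p$shape, p$sigma_pair, p$sigma_ind,
                             gh$x, gh$w, gh$x, gh$w, want_grad)
  }
  negll <- function(theta) -eval_ll(theta, FALSE)$loglik
  # analytic score: beta gradients are design-weighted sums of the
  # per-observation linear-predictor score
  neggrad <- function(theta) {
    r <- eval_ll(theta, TRUE)
    g <- c(r$g_logk, sum(r$g_eta),
           if (nb) drop(crossprod(Xo, r$g_eta)),
           if (est_sp) r$g_logsigma_pair,
           if (est_si) r$g_logsigma_ind)
    -g
  }

  opt <- stats::optim(theta0, negll, neggrad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  hess <- tryCatch(stats::optimHess(opt$par, negll, neggrad),
                   error = function(e) NULL)
  vcov <- if (is.null(hess)) NULL else
    tryCatch(solve(hess), error = function(e) NULL)
  ok_vcov <- !is.null(vcov) && all(is.finite(vcov)) &&
    all(diag(vcov) > 0)
  ph <- unpack(opt$par)
  ph_ok <- all(is.finite(c(ph$shape, ph$beta0, ph$beta, ph$sigma_pair,
                           ph$sigma_ind))) && ph$shape > 0
  converged <- opt$convergence == 0L && ok_vcov && ph_ok
  status <- if (!ph_ok) {
    "estimates diverged (non-finite parameters; non-identifiable or boundary outcome)"
  } else if (opt$convergence != 0L) {
    paste0("optimizer did not converge (code ", opt$convergence, ")")
  } else if (!ok_vcov) {
    "Hessian not positive definite at the optimum (non-identifiable or boundary solution)"
  } else "converged"
  if (!converged) {
    warning("fit flagged: ", status, call. = FALSE)
  }
  if (is.null(vcov)) {
    vcov <- matrix(NA_real_, length(theta0), length(theta0))
  }
  dimnames(vcov) <- list(names(theta0), names(theta0))

  # built without validation so a flagged, diverged fit can still be printed
  params <- structure(
    list(shape = ph$shape, beta0 = ph$beta0,
         beta = stats::setNames(as.numeric(ph$beta), coef_names),
         sigma_pair = ph$sigma_pair, sigma_ind = ph$sigma_ind),
    class = "weibull_frailty_params")

  structure(list(
    params = params, theta = opt$par, loglik = -opt$value, vcov = vcov,
    converged = converged, status = status,
    n_obs = nrow(gs$data), n_subjects = gs$n_subjects, n_pairs = gs$n_pairs,
    quad_nodes = quad_order, frailty = frailty, tol = tol,
    used_levels = used_levels, coef_names = coef_names),
    class = "sleep_weibull_fit")
}

#' @export
print.sleep_weibull_fit <- function(x, ...) {
  cat("Interval-censored Weibull fit with", x$frailty, "frailty\n")
  cat("  ", x$n_obs, "observations,", x$n_subjects, "subjects,",
      x$n_pairs, "pairs;", x$quad_nodes, "quadrature nodes\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " status:", x$status, "\n")
  print(x$params)
  invisible(x)
}

#' Hazard-ratio table from a fitted model
#'
#' Wald hazard ratios and confidence intervals, `exp(beta +/- z * se)`, with
#' a reference row (`hr = 1`, no CI) emitted for each factor's baseline
#' level, mirroring the layout of a published HR table.
#'
#' @param fit A `"sleep_weibull_fit"` object with a valid covariance matrix.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `factor`, `level`, `term`, `hr`, `ci_low`,
#'   `ci_high`, `is_reference`.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sleep_weibull_fit"), level > 0, level < 1)
  if (all(is.na(fit$vcov))) stop("fit has no covariance matrix", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (f in names(fit$used_levels)) {
    lv <- fit$used_levels[[f]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      factor = f, level = lv[1], term = NA_character_, hr = 1,
      ci_low = NA_real_, ci_high = NA_real_, is_reference = TRUE)
    for (l in lv[-1]) {
      term <- paste0(f, l)
      b <- fit$params$beta[[term]]
      se <- sqrt(fit$vcov[term, term])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        factor = f, level = l, term = term, hr = exp(b),
        ci_low = exp(b - z * se), ci_high = exp(b + z * se),
        is_reference = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

resolve_params <- function(object) {
  if (inherits(object, "sleep_weibull_fit")) object$params
  else if (inherits(object, "weibull_frailty_params")) object
  else stop("need a fit or a weibull_frailty_params object", call. = FALSE)
}

# linear predictor for one covariate pattern given as a named list/row
linpred_pattern <- function(params, covariates) {
  cov <- as.list(covariates)
  df <- tibble::tibble(
    birth_cohort = cov$birth_cohort %||% birth_cohort_levels[1],
    age_group = cov$age_group %||% age_group_levels[1],
    gender = cov$gender %||% gender_levels[1])
  for (f in names(df)) {
    lv <- list(birth_cohort = birth_cohort_levels,
               age_group = age_group_levels, gender = gender_levels)[[f]]
    if (!df[[f]] %in% lv) stop("unknown ", f, " level: ", df[[f]],
                               call. = FALSE)
  }
  X <- design_matrix(df)
  keep <- intersect(colnames(X), names(params$beta))
  active <- colnames(X)[X[1, ] != 0]
  unmatched <- setdiff(active, names(params$beta))
  if (length(unmatched)) {
    stop("no coefficient for level(s): ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  params$beta0 + sum(params$beta[keep] * X[1, keep])
}

#' Model-implied survival curve for a covariate pattern
#'
#' Evaluates \eqn{S(t)} on a time grid for a chosen combination of birth
#' cohort, age group and gender. `frailty = "zero"` plugs in random
#' intercepts of zero (the conditional median-frailty curve);
#' `frailty = "marginal"` integrates over both frailty levels by
#' Gauss--Hermite quadrature (the sum of two independent normal intercepts
#' has SD \eqn{\sqrt{\sigma_p^2 + \sigma_i^2}}).
#'
#' @param object A `"sleep_weibull_fit"` or [weibull_frailty_params()].
#' @param covariates Named list with any of `birth_cohort`, `age_group`,
#'   `gender`; omitted factors sit at their reference level.
#' @param t_grid Sorted nonnegative time grid in hours.
#' @param frailty `"zero"` or `"marginal"`.
#' @param quad_order Nodes for the marginal integration.
#' @return A tibble with columns `time`, `surv`, classed
#'   `"sleep_survcurve_pred"`.
#' @export
predict_survival <- function(object, covariates = list(), t_grid,
                             frailty = c("zero", "marginal"),
                             quad_order = 41) {
  frailty <- match.arg(frailty)
  params <- resolve_params(object)
  if (is.unsorted(t_grid) || any(t_grid < 0)) {
    stop("t_grid must be sorted and nonnegative", call. = FALSE)
  }
  lp <- linpred_pattern(params, covariates)
  if (frailty == "zero") {
    s <- weibull_ph_survival(t_grid, lp, params$shape)
  } else {
    sig <- sqrt(params$sigma_pair^2 + params$sigma_ind^2)
    gh <- gh_rule(quad_order)
    w <- gh$w / sum(gh$w)
    u <- sqrt(2) * sig * gh$x
    s <- vapply(t_grid, function(t) {
      sum(w * weibull_ph_survival(t, lp + u, params$shape))
    }, numeric(1))
  }
  out <- tibble::tibble(time = t_grid, surv = s)
  class(out) <- c("sleep_survcurve_pred", class(out))
  attr(out, "frailty") <- frailty
  out
}

#' Model-implied mean sleep duration
#'
#' Closed-form Weibull mean at zero frailty:
#' \eqn{E[T] = \Gamma(1 + 1/k)\, e^{-\eta/k}}.
#'
#' @inheritParams predict_survival
#' @return Mean duration in hours.
#' @examples
#' mean_duration(weibull_frailty_params(shape = 2, beta0 = 0))  # gamma(1.5)
#' @export
mean_duration <- function(object, covariates = list()) {
  params <- resolve_params(object)
  lp <- linpred_pattern(params, covariates)
  gamma(1 + 1 / params$shape) * exp(-lp / params$shape)
}

#' Tidy a fitted Weibull frailty model
#'
#' Broom-style summary of the internal (unconstrained) parameter vector:
#' `log_shape`, `beta0`, the log hazard-ratio coefficients, and
#' `log_sigma_pair` / `log_sigma_ind` where estimated. Wald statistics use
#' the inverse-Hessian covariance.
#'
#' @param x A `"sleep_weibull_fit"` object.
#' @param conf.int Add Wald confidence bounds.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` and optionally `conf.low`, `conf.high`.
#' @export
tidy.sleep_weibull_fit <- function(x, conf.int = TRUE, conf.level = 0.95,
                                   ...) {
  se <- sqrt(diag(x$vcov))
  out <- tibble::tibble(
    term = names(x$theta), estimate = as.numeric(x$theta),
    std.error = as.numeric(se),
    statistic = as.numeric(x$theta / se),
    p.value = 2 * stats::pnorm(-abs(as.numeric(x$theta / se))))
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Glance at a fitted Weibull frailty model
#'
#' @inheritParams tidy.sleep_weibull_fit
#' @return A one-row tibble with `logLik`, `AIC`, `BIC`, `nobs`,
#'   `n_subjects`, `n_pairs`, `quad_nodes`, `converged`.
#' @export
glance.sleep_weibull_fit <- function(x, ...) {
  p <- length(x$theta)
  tibble::tibble(
    logLik = x$loglik, AIC = 2 * p - 2 * x$loglik,
    BIC = p * log(x$n_obs) - 2 * x$loglik,
    nobs = x$n_obs, n_subjects = x$n_subjects, n_pairs = x$n_pairs,
    quad_nodes = x$quad_nodes, converged = x$converged)
}

#' Forest plot of hazard ratios
#'
#' @param object A `"sleep_weibull_fit"`.
#' @param level Confidence level for the intervals.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sleep_weibull_fit <- function(object, level = 0.95, ...) {
  hr <- hazard_ratios(object, level = level)
  hr$label <- paste(hr$factor, hr$level)
  hr$label <- factor(hr$label, rev(hr$label))
  ggplot2::ggplot(hr, ggplot2::aes(x = .data$hr, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2,
      na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (shorter sleep)", y = NULL)
}

#' Serialize a fit to JSON
#'
#' Writes parameters, covariance, log-likelihood, settings and package
#' version in a plain JSON record.
#'
#' @param fit A `"sleep_weibull_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    params = list(shape = fit$params$shape, beta0 = fit$params$beta0,
                  beta = as.list(fit$params$beta),
                  sigma_pair = fit$params$sigma_pair,
                  sigma_ind = fit$params$sigma_ind),
    loglik = fit$loglik,
    theta = as.list(fit$theta),
    vcov = unname(apply(fit$vcov, 1, as.list, simplify = FALSE)),
    vcov_names = names(fit$theta),
    converged = fit$converged, status = fit$status,
    n_obs = fit$n_obs, n_subjects = fit$n_subjects, n_pairs = fit$n_pairs,
    settings = list(quad_nodes = fit$quad_nodes, frailty = fit$frailty,
                    tol = fit$tol),
    tool_version = as.character(utils::packageVersion("twinsleep")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
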