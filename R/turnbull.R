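#' Innermost (Turnbull) intervals of interval-censored data
#'
#' The nonparametric MLE for interval-censored data places all its mass on
#' the maximal intersections of the observation intervals: sets `[l, r)`
#' with `l` some observation's left endpoint, `r` some observation's right
#' endpoint, and no other observation endpoint strictly inside. Ties on
#' equal endpoints follow the half-open `[l, r)` convention.
#'
#' @param left,right Numeric vectors of interval bounds (`right` may be
#'   `Inf`).
#' @return A tibble with columns `left`, `right`, ordered by `left`.
#' @examples
#' turnbull_sets(c(0, 1), c(2, 3))   # innermost set [1, 2)
#' @export
turnbull_sets <- function(left, right) {
  stopifnot(length(left) == length(right), length(left) >= 1,
            all(left < right))
  ls <- sort(unique(left))
  rs <- sort(unique(right))
  ends <- sort(unique(c(ls, rs)))
  out_l <- numeric(0)
  out_r <- numeric(0)
  for (l in ls) {
    # smallest right endpoint > l; innermost iff no endpoint strictly between
    r_cand <- rs[rs > l]
    if (!length(r_cand)) next
    r <- r_cand[1]
    if (!any(ends > l & ends < r)) {
      # must be the intersection of some observation pair: some obs has left
      # endpoint l, some obs has right endpoint r, and [l, r) is inside both
      if (any(left <= l & right >= r)) {
        out_l <- c(out_l, l)
        out_r <- c(out_r, r)
      }
    }
  }
  tibble::tibble(left = out_l, right = out_r)
}

#' Turnbull nonparametric MLE of the survival function
#'
#' Self-consistency (EM) estimate of the survival function from
#' interval-censored observations, with uniform mass initialisation over the
#' innermost intervals. Each E-step allocates every observation's unit mass
#' across the innermost sets it contains in proportion to the current
#' masses; the M-step averages. The observed-data log-likelihood
#' \eqn{\sum_i \log \sum_{s \subseteq I_i} m_s} is nondecreasing across
#' iterations. Within an innermost interval the estimator is undefined; the
#' reported curve stays flat and drops at the set's right endpoint.
#'
#' @inheritParams turnbull_sets
#' @param tol Convergence tolerance on the largest absolute mass change.
#' @param max_iter Iteration cap; reaching it flags the result.
#' @return An object of class `"sleep_npmle"`: a list with `sets` (tibble of
#'   `left`, `right`, `mass`), `curve` (tibble `time`, `surv` starting at
#'   `(0, 1)`), `loglik` (final value), `loglik_path` (per iteration),
#'   `converged`, `n_iter`, `n`.
#' @export
npmle <- function(left, right, tol = 1e-8, max_iter = 10000) {
  sets <- turnbull_sets(left, right)
  n <- length(left)
  ns <- nrow(sets)
  # membership: set s is inside observation i
  A <- outer(left, sets$left, `<=`) & outer(right, sets$right, `>=`)
  if (any(rowSums(A) == 0)) {
    stop("an observation contains no innermost set; invalid intervals",
         call. = FALSE)
  }
  m <- rep(1 / ns, ns)
  ll_path <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p_i <- drop(A %*% m)
    ll_path <- c(ll_path, sum(log(p_i)))
    m_new <- drop(crossprod(A, 1 / p_i)) * m / n
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  p_i <- drop(A %*% m)
  ll_path <- c(ll_path, sum(log(p_i)))

  sets$mass <- m
  # step curve at category boundaries: flat within a set, drop at its right
  # endpoint; an infinite right endpoint leaves the tail at its mass level
  finite <- is.finite(sets$right)
  times <- c(0, sets$right[finite])
  surv <- c(1, 1 - cumsum(sets$mass)[finite])
  surv <- pmin(pmax(surv, 0), 1)
  curve <- tibble::tibble(time = times, surv = surv)
  structure(list(sets = sets, curve = curve,
                 loglik = ll_path[length(ll_path)], loglik_path = ll_path,
                 converged = converged, n_iter = iter, n = n),
            class = "sleep_npmle")
}

#' @export
print.sleep_npmle <- function(x, ...) {
  cat("Turnbull NPMLE on", x$n, "interval-censored observations\n")
  cat("  ", nrow(x$sets), "innermost sets;", x$n_iter, "EM iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$sets)
  invisible(x)
}

#' Midpoint-reduction Kaplan--Meier curve
#'
#' Reduces interval-censored categories to point data — finite intervals to
#' their midpoints, right-censored categories to censoring times at their
#' left bound — and computes the standard product-limit estimator. Provided
#' for comparison with the censoring-aware Turnbull estimate, since grouped
#' survey curves are conventionally displayed as Kaplan--Meier plots.
#'
#' @inheritParams turnbull_sets
#' @return A tibble with columns `time`, `surv`, starting at `(0, 1)`.
#' @export
km_midpoint <- function(left, right) {
  stopifnot(length(left) == length(right), all(left < right))
  event <- is.finite(right)
  time <- ifelse(event, (left + right) / 2, left)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble::tibble(time = c(0, sf$time), surv = c(1, sf$surv))
}

#' Nonparametric survival curves by group
#'
#' Convenience wrapper computing one survival curve per group of an
#' enriched response table (for example one curve per survey wave, the
#' classic four-wave sleep-duration figure).
#'
#' @param data Enriched response tibble (see [as_sleep_responses()]).
#' @param by Column to group by (character), default `"wave_year"`.
#' @param method `"turnbull"` (default) or `"km_midpoint"`.
#' @param tol,max_iter Passed to [npmle()].
#' @return A long tibble with columns `group`, `time`, `surv`, classed
#'   `"sleep_survcurves"`.
#' @export
survival_curves <- function(data, by = "wave_year",
                            method = c("turnbull", "km_midpoint"),
                            tol = 1e-8, max_iter = 10000) {
  method <- match.arg(method)
  stopifnot(by %in% names(data))
  groups <- split(data, data[[by]])
  out <- purrr::map_dfr(names(groups), function(g) {
    d <- groups[[g]]
    cur <- if (method == "turnbull") {
      npmle(d$left, d$right, tol = tol, max_iter = max_iter)$curve
    } else {
      km_midpoint(d$left, d$right)
    }
    dplyr::mutate(cur, group = g, .before = 1)
  })
  class(out) <- c("sleep_survcurves", class(out))
  attr(out, "method") <- method
  attr(out, "by") <- by
  out
}

#' Step plot of grouped survival curves
#'
#' @param object A `"sleep_survcurves"` tibble from [survival_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sleep_survcurves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Sleep duration (hours)",
                  y = "Proportion sleeping at least this long",
                  colour = attr(object, "by"))
}
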