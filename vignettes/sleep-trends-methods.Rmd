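---
title: "Modelling ordinal sleep-duration reports as interval-censored survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ordinal sleep-duration reports as interval-censored survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinsleep)
```

## The problem

Population cohorts that track sleep duration over decades almost never have
it as a continuous measurement. Mailed questionnaires offer a short list of
ordinal alternatives ("7", "7.5", "10 h or more"), the list changes between
survey rounds, and respondents round to the nearest offered value. Treating
the chosen category as an exact number discards the information about *how*
coarse each round's instrument was, and biases comparisons between rounds
with different category widths.

`twinsleep` takes the alternative route: each response is an
**interval-censored** observation of a latent continuous sleep duration. A
response of "7" on a one-hour instrument says only that the latent duration
lies in [6.5, 7.5) hours; "6 h or less" is a left-censored observation and
"10 h or more" a right-censored one. The four survey waves modelled here
(1975, 1981, 1990, 2011) use two instruments: seven one-hour alternatives in
1975 (`coarse1975`) and nine half-hour alternatives afterwards
(`half_hour`). Interior categories are centred on their stated value; the
open ends absorb the tails so each scheme tiles $(0, \infty)$ with no gaps.
Category boundaries are a modelling choice, not data; they are serializable
(`write_schemes()`) so alternatives can be explored without code changes.
One genuinely ambiguous point: the 1975 instrument offered "less than 4 h"
but no plain "4", so the lowest category is taken as $(0, 4.5)$, which is
compatible with both readings of that label and preserves the one-hour
tiling.

## The model

The latent duration $T$ follows a Weibull proportional-hazards model with
nested normal random intercepts on the log-hazard scale:

$$
h(t \mid x, u) = k\, t^{k-1} \exp(\beta_0 + x'\beta + u_{\text{pair}} +
u_{\text{ind}}), \qquad
S(t \mid x, u) = \exp\!\big(-t^{k} e^{\beta_0 + x'\beta + u_{\text{pair}} +
u_{\text{ind}}}\big),
$$

with $u_{\text{pair}} \sim N(0, \sigma_p^2)$ shared by both members of a
twin pair and $u_{\text{ind}} \sim N(0, \sigma_i^2)$ shared by one person's
repeated responses across waves. The covariates are three factors: birth
cohort (<1900 reference, 1900–1919, 1920–1939, 1940–1957), age group at the
survey (18–34 reference, 35–54, 55+) and gender (female reference). Because
the model is proportional hazards, $e^{\beta}$ is a hazard ratio **for
shorter sleep**: a value above 1 means the latent duration tends to end
sooner. Age group and birth cohort are partially confounded by construction
(age = survey year − birth year); both are kept in the model because the
longitudinal design separates them, and the fitter only refuses exact rank
deficiency.

A response in category $[l, r)$ contributes $S(l) - S(r)$ conditional on
the random intercepts; the half-open convention is immaterial for a
continuous latent variable. The marginal likelihood of a pair integrates
over both frailty levels,

$$
L_{\text{pair}} = \int \phi(u_p; \sigma_p) \prod_{j}
\int \phi(u_j; \sigma_i) \prod_{i} \big[S(l_{ij}) - S(r_{ij})\big]
\, du_j \, du_p,
$$

evaluated by non-adaptive nested Gauss–Hermite quadrature (default 25
nodes per level, configurable; the compiled evaluator also returns the
analytic score, assembled from posterior node weights). With
$\sigma_p = \sigma_i = 0$ the quadrature weights sum to one and the
expression reduces *exactly* to the fixed-effects interval-censored
likelihood — this identity is tested to $10^{-10}$, and the quadrature is
tested against brute-force Monte Carlo integration on small instances.

The published analysis this package re-implements reported its results as
hazard ratios but did not print its likelihood; the proportional-hazards
parameterisation, the log-normal (normal-on-log-hazard) frailty, and the
presence of both a pair and an individual level are therefore this
package's own definition, chosen because hazard ratios are the reported
scale, normal intercepts integrate cleanly with Gauss–Hermite, and
repeated measurements on the same persons warrant a within-person level.
Either frailty level can be switched off (`frailty = "pair"`, `"none"`,
...).

## Estimation and numerical choices

* **Scale.** Optimisation runs on the unconstrained vector
  $(\log k, \beta_0, \beta, \log \sigma_p, \log \sigma_i)$ by BFGS with the
  analytic gradient. Starting values: a censoring-ignorant moment fit of
  $(k, \beta_0)$ from midpoint-coded durations, zero coefficients, frailty
  SDs of 0.1.
* **Convergence.** The fit is declared converged when the optimiser meets
  its relative-tolerance criterion (`tol`, default $10^{-8}$) *and* the
  numerical Hessian at the optimum is finite and positive definite. A
  gradient-norm criterion was considered and rejected: the likelihood has
  magnitude $\sim 10^4$ on realistic cohorts, so a fixed small gradient
  norm sits below the attainable numerical noise floor. Non-convergence,
  boundary solutions and diverged parameters are flagged in `status`,
  never silent.
* **Zero-probability intervals.** During line searches a parameter value
  can push an interval's probability below the double floor; such terms
  contribute a large finite penalty ($\log 10^{-300}$ with zero score)
  instead of $-\infty$, keeping quasi-Newton steps stable. The reported
  optimum is re-evaluated exactly.
* **Uncertainty.** `vcov` is the inverse numerical Hessian on the
  unconstrained scale; hazard-ratio intervals are Wald intervals
  $\exp(\hat\beta \pm z\,\mathrm{se})$. `predict_survival(...,
  frailty = "marginal")` integrates the curve over the combined frailty
  ($\sqrt{\sigma_p^2 + \sigma_i^2}$, one-dimensional Gauss–Hermite),
  `"zero"` plugs in $u = 0$.
* **Determinism.** No random restarts; identical data and settings give
  identical fits.

## Nonparametric curves

`npmle()` implements the Turnbull self-consistency (EM) estimator for
interval-censored data: mass lives only on the innermost intervals
(maximal intersections of observation intervals), initialisation is
uniform, and the observed-data log-likelihood is checked to be
nondecreasing across iterations in the tests. Within an innermost interval
the NPMLE is undefined; curves are drawn flat and drop at the interval's
right endpoint — a conventional, conservative display. `km_midpoint()`
reduces categories to midpoints (right-censored categories to censoring
times) and applies the standard product-limit estimator via the survival
package, because grouped survey curves are conventionally displayed as
Kaplan–Meier plots; which of the two a published figure used is often
unstated, so both are provided and the wave-level default is the
censoring-aware NPMLE.

## Descriptive summaries

`summarize_sleep()` reproduces questionnaire-table summaries by midpoint
coding: interior categories take their stated value, open categories take
a policy value (default `boundary_value`: 4.0, 6.0 and 10.0 — the value
the label names). Midpoint coding is used *only* for descriptive means and
trend statistics; the likelihood never sees it. The discretization bias of
a midpoint-coded mean is bounded by half the category width, and the
acceptance checks compare simulated stratum means against the analytically
computed expected midpoint value (model mean plus discretization bias)
rather than against the latent mean. `trend_minutes_per_year()` converts a
change in mean hours between two survey years into minutes per follow-up
year exactly; published minute conversions of this kind are sometimes
internally inconsistent with their own tabulated means, and this package
deliberately computes the arithmetic correctly rather than reproducing any
specific printed rounding.

## The synthetic cohort generator

The cohort behind the original analysis is not publicly deposited, so the
package ships a generator that emulates its design and makes every stage
testable end to end:

* same-gender twin pairs sharing a birth year, drawn uniformly over
  1880–1957 (the real age pyramid is deliberately not reproduced);
* four waves with the published eligibility windows (1990 restricted to
  births 1930–1957, 2011 to 1945–1957, everyone aged 18+) and the
  published response rates (89%, 84%, 77%, 72%) as independent Bernoulli
  participation — no dropout correlation, mortality or attrition linkage
  between waves;
* latent durations drawn by inverse CDF from the Weibull frailty model
  and discretized with the wave's scheme.

`default_truth()` uses the published hazard-ratio point estimates
(1.11, 1.41, 1.62; 1.24, 1.23; 1.13) as generating coefficients and
calibrates $(k, \beta_0)$ so the reference stratum has latent mean 7.69 h
and SD 0.9 h (solving the Weibull coefficient-of-variation equation; this
gives $k \approx 10.2$). Frailty SDs default to 0.25 (pair) and 0.20
(individual): the original report contains no frailty variances, so these
are this package's own choice of a plausible within-pair correlation, and
the recovery tests treat them as free truth parameters.

Randomness uses one substream per pair, keyed by (seed, pair index), so
enlarging a cohort never reshuffles the pairs already drawn; each pair's
draw block has fixed length regardless of participation outcomes.

What passing tests therefore do and do not show: they demonstrate that the
estimation machinery recovers known generating values under the study's
design — sample sizes, censoring schemes, eligibility and response rates —
not that the original cohort's printed estimates are reproduced, which is
impossible without the data. Real questionnaire data additionally contain
digit preference beyond the offered categories, non-ignorable nonresponse,
reporting heterogeneity by age, and cohort-specific age pyramids, none of
which the generator emulates.

## Problem sizes used by the shipped checks

The test suite exercises parameter recovery on 20 replicate cohorts of
2000 pairs at 15 quadrature nodes (about 8,000–8,500 observations each),
checking that the 95% Wald intervals cover each generating hazard ratio in
at least 90% of replicates and that the mean absolute relative error of
the six hazard-ratio estimates stays under 10%. Likelihood correctness is
checked against 200,000-draw Monte Carlo integration on instances of up to
8 pairs and 30 observations. `scripts/acceptance.R` runs one 2000-pair
cohort end to end. These sizes were chosen as the smallest that make the
coverage and error bounds statistically meaningful.

## A short tour

```{r tour, eval = FALSE}
sim <- simulate_cohort(sim_config(n_pairs = 500, seed = 1))
data <- as_sleep_responses(sim$responses)

summarize_sleep(data, "wave_gender")
autoplot(survival_curves(data, by = "wave_year"))

fit <- fit_weibull_frailty(data, quad_order = 15)
hazard_ratios(fit)
tidy(fit)
glance(fit)
predict_survival(fit, list(age_group = "55+", birth_cohort = "1940-1957"),
                 t_grid = seq(0, 12, 0.25), frailty = "marginal")
```

## Known limitations

* The likelihood definition follows this package's proportional-hazards,
  log-normal-frailty reconstruction; a different frailty law or estimation
  scheme in the original analysis would yield different (if similar)
  estimates.
* Non-adaptive quadrature: with very large frailty SDs (well beyond the
  defaults) the fixed node grid loses accuracy; raise `quad_order` in that
  regime (a 15- vs 35-node refit is tested to move coefficients by less
  than $10^{-3}$ at realistic SDs).
* Ages are computed as survey year minus birth year; month-level precision
  does not exist in the source design.
* No survey weights, nonresponse adjustment, zygosity information or
  within-wave time-varying covariates; confidence bands for the NPMLE are
  not provided.
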