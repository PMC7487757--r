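# twinsleep

Long-run trends in self-reported sleep duration, estimated the way the data
actually arrive: as ordinal questionnaire categories, not continuous hours.

`twinsleep` is for epidemiologists and biostatisticians working with
repeated mailed-survey cohorts — here, a twin cohort surveyed four times
over 36 years (1975, 1981, 1990, 2011) — where sleep duration was asked
with wave-specific response alternatives (seven one-hour categories in
1975, nine half-hour categories later). The package treats each response as
an **interval-censored** observation of a latent continuous duration and
fits a **Weibull proportional-hazards regression with nested random
effects** for twin pair and individual:

$$h(t \mid x, u) = k\,t^{k-1} \exp(\beta_0 + x'\beta + u_{\mathrm{pair}} + u_{\mathrm{ind}}),
\qquad u_{\mathrm{pair}} \sim N(0,\sigma_p^2),\; u_{\mathrm{ind}} \sim N(0,\sigma_i^2),$$

so that $e^{\beta}$ is a hazard ratio *for shorter sleep* across birth
cohorts, age groups and genders. The marginal likelihood integrates both
frailty levels by nested Gauss–Hermite quadrature (compiled, with analytic
gradient). Around the model sit:

* **Turnbull NPMLE** survival curves for interval-censored categories
  (`npmle()`, `survival_curves()`), plus midpoint Kaplan–Meier for
  comparison;
* **descriptive tables and trends** from midpoint-coded categories
  (`summarize_sleep()`, `trend_minutes_per_year()`);
* a **synthetic twin-cohort generator** (`simulate_cohort()`) mirroring the
  survey design — same-gender pairs, wave-specific eligibility and response
  rates, wave-specific response schemes — since the original cohort data
  are not publicly deposited;
* a one-call **pipeline** (`run_pipeline()`) writing all tables, curves and
  the fitted model to disk.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fits, `autoplot()` on fits and curve sets.

## Worked example

```r
library(twinsleep)

sim  <- simulate_cohort(sim_config(n_pairs = 500, seed = 1))
data <- as_sleep_responses(sim$responses)

summarize_sleep(data, "wave_gender")
#> # A tibble: 8 × 5
#>   wave_year stratum     n mean_hours sd_hours
#>       <int> <chr>   <int>      <dbl>    <dbl>
#> 1      1975 female    490       7.46    0.950
#> 2      1975 male      407       7.30    0.969
#> 3      1981 female    472       7.40    0.845
#> 4      1981 male      381       7.44    0.841
#> # ℹ 4 more rows

fit <- fit_weibull_frailty(data, quad_order = 15)
hazard_ratios(fit)
#> # A tibble: 9 × 7
#>   factor       level     term                     hr ci_low ci_high is_reference
#>   <chr>        <chr>     <chr>                 <dbl>  <dbl>   <dbl> <lgl>
#> 1 birth_cohort <1900     <NA>                   1    NA       NA    TRUE
#> 2 birth_cohort 1900-1919 birth_cohort1900-1919  1.03  0.883    1.21 FALSE
#> 3 birth_cohort 1920-1939 birth_cohort1920-1939  1.20  0.999    1.44 FALSE
#> 4 birth_cohort 1940-1957 birth_cohort1940-1957  1.31  1.08     1.61 FALSE
#> 5 age_group    18-34     <NA>                   1    NA       NA    TRUE
#> 6 age_group    35-54     age_group35-54         1.09  0.917    1.30 FALSE
#> 7 age_group    55+       age_group55+           1.00  0.818    1.23 FALSE
#> 8 gender       female    <NA>                   1    NA       NA    TRUE
#> 9 gender       male      gendermale             1.11  1.00     1.24 FALSE

glance(fit)
#> # A tibble: 1 × 8
#>   logLik   AIC   BIC  nobs n_subjects n_pairs quad_nodes converged
#>    <dbl> <dbl> <dbl> <int>      <int>   <int>      <dbl> <lgl>
#> 1 -3508. 7036. 7093.  2125        987     500         15 TRUE

mean_duration(fit)   # model-implied reference-stratum mean, hours
#> [1] 7.50...
```

Reading the output: the `hr` column is the multiplicative effect on the
hazard of the latent sleep duration ending — `hr > 1` means shorter sleep.
In this 500-pair simulation the 1940–1957 birth cohort sleeps shorter than
the pre-1900 reference (HR 1.31, 95% CI 1.08–1.61), and men sleep slightly
shorter than women (HR 1.11); at this sample size the age-group effects are
not yet distinguishable from 1, and a 2000-pair cohort recovers all six
generating hazard ratios (see the tests). `mean_duration()` converts the
fitted parameters back to the hours scale via
$E[T] = \Gamma(1 + 1/k)\,e^{-\eta/k}$.

Nonparametric wave curves, and model-implied curves for any covariate
pattern:

```r
autoplot(survival_curves(data, by = "wave_year"))
predict_survival(fit, list(age_group = "55+", birth_cohort = "1940-1957"),
                 t_grid = seq(0, 12, 0.25), frailty = "marginal")
```

## Documentation

The methods vignette (`vignettes/sleep-trends-methods.Rmd`) documents the
model and its assumptions, the numerical choices (quadrature, optimisation,
penalties, category-boundary conventions), what the synthetic generator
does and does not emulate, and known limitations.
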