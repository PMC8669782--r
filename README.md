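# cmburden

Age-specific relative risks of cardiovascular disease from pooled prospective
cohorts, and the cardiovascular deaths attributable to non-optimal
cardio-metabolic risk factor levels.

`cmburden` implements the analytic chain used by pooled-cohort consortia to
turn harmonised participant-level data on body mass index (BMI, kg/m²),
systolic blood pressure (SBP, mmHg), fasting plasma glucose (FPG, mmol/L),
total cholesterol (TC, mmol/L) and non-HDL cholesterol (mmol/L) into
population-level burden estimates:

1. **Pooling and person-time** — participant tables from many cohorts are
   harmonised to canonical units and each participant's follow-up is split
   (Lexis expansion) into attained-age bands 35–44, …, 85+, so events and
   person-time are attributed to the age at which they occur.
2. **Multiple imputation** — missing exposures are imputed by chained
   equations with predictive mean matching; models are fitted in each of the
   *m* completed datasets and pooled by Rubin's rules
   (T = W̄ + (1 + 1/m)·B, with the standard degrees-of-freedom formula).
3. **Regression-dilution correction** — repeat measurements give the
   regression-dilution ratio λ by the MacMahon grouped-quantile-means
   method; log relative risks per one-off baseline measurement are rescaled
   by 1/λ to refer to *usual* exposure.
4. **Age-band incidence models** — within each age band, event counts on
   person-time segments follow a Poisson random-intercept model,
   log μ = log(person-time) + β·x + γ₁·sex + γ₂·(age − band midpoint) + u_cohort,
   u_cohort ~ N(0, σ²_u), fitted by adaptive Gauss–Hermite quadrature. β is
   the log incidence-rate ratio per canonical exposure unit.
5. **Comparative risk assessment** — band RRs are interpolated to 5-year age
   groups, combined with country × sex × age mean exposure levels and an
   optimal (theoretical-minimum-risk) counterfactual mean. Under a log-linear
   RR and a pure mean shift the population attributable fraction is exactly
   PAF = 1 − exp(−β·Δ), Δ = max(0, mean − optimal). PAFs times stratum
   deaths give attributable deaths, crude rates per 100,000, sub-regional
   aggregates, premature (ages 20–69) to all-ages (20+) ratios, and Monte
   Carlo credible intervals from the RR uncertainty.

Real consortium data are access-restricted, so the package ships a
synthetic multi-cohort generator (`simulate_cohorts()`) with known
ground-truth effects, attenuation, baseline rates and missingness, plus a
packaged table of published sub-regional attributable-death estimates
(`lac_attributable_deaths_2019()`) to exercise the reporting arithmetic.

## Worked example

```r
library(cmburden)
library(dplyr)

# synthetic pooled cohort set with known truth
sim  <- simulate_cohorts(sim_config(n_cohorts = 10, n_per_cohort = 500, seed = 7))
pool <- pool_cohorts(list(sim = sim$participants))
crude_rate(sum(pool$event_fatal), sum(pool$followup_time))
#> # A tibble: 1 × 5
#>   events person_years  rate ci_low ci_high
#>    <int>        <dbl> <dbl>  <dbl>   <dbl>
#> 1     67       44587.  150.   116.    191.
```

67 fatal events over 44,587 person-years is a crude rate of 150 (exact
Poisson 95% CI 116–191) per 100,000 person-years.

```r
# dilution correction from the repeat measurements, then age-band models
lambda <- estimate_correction_factors(sim, "sbp")   # MacMahon, pooled over cohorts
seg    <- lexis_expand(pool, outcome = "fatal")
fits   <- fit_age_band_models(seg, "sbp", nAGQ = 7)
rr     <- assemble_rrs(fits, correction = lambda, increment = 10,
                       risk_factor = "sbp")
rr %>% select(band, rr, ci_low, ci_high)
#> band 85+ skipped: no events in this band: nothing to fit.
#> # A tibble: 5 × 4
#>   band     rr ci_low ci_high
#>   <chr> <dbl>  <dbl>   <dbl>
#> 1 35-44 1.17   0.327    4.21
#> 2 45-54 1.38   0.834    2.29
#> 3 55-64 0.898  0.613    1.32
#> 4 65-74 0.899  0.639    1.26
#> 5 75-84 1.15   0.754    1.75
```

The `rr` column is the dilution-corrected relative risk per 10 mmHg of
usual SBP in each attained-age band (the MacMahon factor estimated from
this set's own repeats is 1.49; intervals are wide because the toy set has
only 67 fatal events). `interpolate_rr_5y(rr)` carries these to 5-year age
groups, and `compute_burden()` / `monte_carlo_ci()` turn them into
attributable deaths with credible intervals; `run_pipeline(pipeline_config(...))`
executes the whole chain file-to-file with a run manifest.

Published premature-to-all-ages ratios are reproduced by the reporting
arithmetic:

```r
premature_ratio(2659, 3299)   # 80.60 % (attributable BMI deaths, Andean men)
#> [1] 80.60018
```

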