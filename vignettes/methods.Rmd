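---
title: "Methods: pooled-cohort relative risks and attributable cardiovascular burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-cohort relative risks and attributable cardiovascular burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmburden)
```

`cmburden` estimates age-specific relative risks (RRs) of cardiovascular
disease for cardio-metabolic risk factors from pooled prospective cohort
data, and converts those RRs into population attributable fractions (PAFs)
and attributable cardiovascular deaths by country, sex and age. This
vignette is the package's account of the statistical machinery: the models,
the tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## The data model

The unit of analysis is a participant record: cohort membership, sex,
baseline age (eligibility requires age ≥ 20), baseline exposures in
canonical units (BMI kg/m², SBP mmHg, FPG/TC/non-HDL mmol/L), follow-up
time, fatal and non-fatal event indicators, and optional repeat exposure
measurements. `pool_cohorts()` harmonises heterogeneous source tables:
exposures are converted to canonical units (cholesterol mg/dL ÷ 38.67,
glucose mg/dL ÷ 18.016), identifiers are prefixed by source so pooled keys
stay unique, and rows failing eligibility invariants are dropped and
counted rather than silently lost.

Two outcome definitions are supported, mirroring how consortia with
heterogeneous ascertainment analyse events: `"fatal"` (fatal events only —
available in most cohorts) and `"combined"` (fatal or non-fatal, with
follow-up ending at the first event).

## Person-time: Lexis expansion

Age-specific modelling requires events and person-time attributed to the
age at which they occur, not the age at entry. `lexis_expand()` splits each
record into segments by the attained-age bands 35–44, 45–54, 55–64, 65–74,
75–84, 85+. Choices made here:

* Bands are half-open `[a, b)` intervals in exact fractional years; ages
  are continuous and never rounded, so person-time conserves exactly and
  boundary ages cannot be double-counted.
* Person-time before age 35 is discarded (the youngest modelled band starts
  at 35); records wholly below 35 contribute nothing.
* The event is attributed to the band containing the exit age. When the
  exit falls exactly on a band edge, the occupied interval in the upper
  band is empty, so the event belongs to the last band with positive
  person-time.
* The `age_at_risk` covariate is the midpoint of the occupied sub-interval
  of the band — a documented convention where "age at risk" alone would be
  ambiguous.

Crude rates use the exact Poisson (Garwood) chi-square interval on the
event count, scaled by person-years. The choice of an exact rather than
normal-approximation interval is deliberate: at a few dozen events the two
differ visibly, and the exact interval has the cleaner small-count
behaviour (closed-form lower bound −ln 0.975 per unit person-time at one
event).

## Missing exposures

Cohorts differ in which exposures their protocols measured, so missingness
is dominated by whole variables absent from whole cohorts, with a smaller
within-cohort component. The imputation model (`mi_impute()`) is a
fully-conditional-specification (chained equations) scheme:

* each incomplete exposure is regressed on all other exposures, sex,
  baseline age, cohort indicators, the event indicator and log follow-up
  time — including the outcome and exposure-time term keeps the imputation
  model compatible with the analysis model;
* continuous draws use predictive mean matching (PMM) with k = 5 donors
  and Bayesian parameter draws (posterior σ², then β given σ²). PMM only
  ever imputes observed values, so it cannot produce physiologically
  impossible exposures and is robust to non-normality;
* 10 cycles per imputation (default), m = 50 imputations by default —
  tests and examples use smaller m for speed; m is a user knob;
* a variable missing for every record cannot be imputed and is excluded
  with a warning rather than guessed at.

Where cohort-level missingness makes some cohort indicators inestimable in
an imputation regression (no observed outcome values in that cohort), the
design is reduced to its pivoted full-rank column set and unseen cohorts
fall to the reference level — the pragmatic standard behaviour for
fixed-effect predictors under systematically missing blocks. A multilevel
imputation model with cohort random effects would be the fuller treatment
and is out of scope.

Per-imputation estimates are pooled with `rubin_pool()`: pooled point =
mean; total variance `T = W + (1 + 1/m) B` with `W` the mean
within-imputation variance and `B` the between-imputation variance;
degrees of freedom `(m − 1)(1 + W/((1 + 1/m)B))²`, infinite when `B = 0`.
With nothing missing the stack is m identical copies and pooling returns
the complete-data fit exactly. A complete-case mode (`complete_cases()`,
`complete_case = TRUE` in the pipeline) is provided as the usual
sensitivity analysis.

## Regression dilution

A one-off baseline measurement understates the association with *usual*
exposure because of within-person variability; the attenuation factor is
the regression-dilution ratio λ = σ²_between / (σ²_between + σ²_within).
`macmahon_rdr()` estimates λ the classical way: pairs are grouped into
baseline quintiles (n_groups configurable; the method's tradition is 5),
and λ is the least-squares slope of repeat-measurement group means on
baseline group means. With 2 groups this is the range ratio. Where
multiple repeats exist, the first repeat at least 1 year from baseline is
used, avoiding short-interval correlated error.

Per-cohort estimates are pooled as the pair-count-weighted mean
(`pool_rdr()`); pooling all pairs jointly is also possible by passing the
combined pair table to `macmahon_rdr()` directly — the two conventions
differ only in weighting and both are exposed because neither is canonical.

The correction multiplies the log RR *and its standard error* by 1/λ,
treating the factor as fixed. This is the conventional reporting choice:
CI widths scale proportionally on the log scale, and uncertainty in λ
itself is not propagated. A packaged default factor table
(`default_correction_factors()`: 1.10 BMI, 1.50 SBP, 1.53 FPG, 1.75 TC,
1.85 non-HDL) is used when no repeat data are supplied.

## Age-band incidence models

Within each band, event counts on person-time segments follow

log E[events] = log(person-time) + β·exposure + γ₁·sex + γ₂·(age_at_risk − band midpoint) + u_cohort,

with u_cohort ~ N(0, σ²_u) integrated out by adaptive Gauss–Hermite
quadrature (7 points by default; Laplace as fallback — the contract is the
marginal likelihood, not a particular algorithm; fits are delegated to
`lme4::glmer`). Numerical choices:

* the exposure is centred before fitting (slope unchanged, conditioning
  much improved — SBP values near 131 otherwise swamp the intercept);
* the age covariate is centred at the band midpoint so the intercept is a
  band-level log rate;
* bands with no events, a single cohort, or a constant exposure are
  degenerate and are skipped (band sweep) or rejected (single fit) with
  the reason named;
* convergence is judged from the optimiser's own status; fits that fail to
  converge are flagged and excluded from pooling rather than averaged in.

β is stored per canonical unit; display increments (e.g. per 10 mmHg) are
applied only at assembly time (`assemble_rrs()`), which Rubin-pools β
across imputations, applies the dilution factor on the log scale,
exponentiates at the increment and builds t-based intervals with Rubin
degrees of freedom. `stratified_rrs()` refits the identical machinery
within cohort strata (e.g. geographic sub-regions), skipping strata with
fewer than two cohorts.

Sex-specific RRs are not produced: the models adjust for sex, and the
burden stage applies the same age-specific RRs to both sexes while keeping
exposures and deaths sex-specific.

## Comparative risk assessment

`interpolate_rr_5y()` anchors each 10-year band estimate at the band
midpoint (40, 50, 60, 70, 80; the open-ended 85+ band at 90), interpolates
log RR linearly in age between anchors, and evaluates at the 5-year group
reference ages 20, 25, …, 85. Putting the reference ages on the
multiple-of-5 grid makes every interior band anchor an exact fixed point
of the interpolation — the band estimate is returned unchanged at 40, 50,
…, 80 — which is the property the downstream tests pin. Outside the
anchors the surface is flat: ages 20–34 carry the youngest band's RR
(burden is computed from age 20 but RRs are only estimable from 35; flat
extrapolation is the one self-consistent completion, and it is the main
modelling assumption for the youngest groups), and the 85+ group is
evaluated at 85 between the 80 and 90 anchors. Standard errors are
interpolated the same way.

The PAF uses a mean-shift counterfactual: the population mean moves to the
optimal level, the spread is unchanged. For a log-linear RR the exposure
distribution then cancels in the ratio of expected risks, so

PAF = 1 − exp(−β Δ), Δ = max(0, mean − optimal)

is *exact* for this counterfactual, not an approximation — the package
tests verify closed form against numerical integration of
∫ RR(x) p(x) dx to 10⁻⁶. Populations at or below the optimal level
contribute zero. Default optimal levels (BMI 21 kg/m², SBP 115 mmHg,
TC 3.8 mmol/L, non-HDL 2.6 mmol/L) are conventional theoretical-minimum
values of the comparative-risk-assessment tradition and are required,
overridable inputs. FPG is excluded from the burden stage because no
population exposure surface is available for it.

Attributable deaths are PAF × stratum deaths; crude rates divide by the
adult population (per 100,000); sub-regional aggregation sums deaths and
populations and recomputes the rate from the sums (algebraically the
population-weighted mean of country rates); the premature-to-all-ages
ratio is 100 × (attributable deaths at ages 20–69) / (ages 20+).

Credible intervals (`monte_carlo_ci()`) propagate RR uncertainty only:
each 5-year log RR is drawn from Normal(point, se) — 1,000 draws by
default — and the whole PAF → deaths → rate → ratio chain is recomputed
per draw; intervals are the 2.5th/97.5th percentiles. Exposure-surface and
death-count uncertainty are not propagated; intervals are therefore
narrower than a full uncertainty budget would give.

## The synthetic cohort generator

No consortium microdata are distributable, so every stage is exercised on
`simulate_cohorts()` output with known truth. The generator emulates:

* cohort-level baseline-rate heterogeneity (log-normal random intercepts,
  SD 0.3 by default);
* between- vs within-person exposure variability with a known attenuation:
  default means and total SDs are realistic pooled-cohort values
  (BMI 27.2 ± 4.8 kg/m², SBP 131 ± 22.1 mmHg, FPG 5.5 ± 1.9 mmol/L,
  TC 5.3 ± 1.3, non-HDL 4.2 ± 1.3 mmol/L), and the split is chosen so the
  implied regression-dilution factors equal the conventional 1.10 / 1.50 /
  1.53 / 1.75 / 1.85 — the dilution stage can therefore be validated
  against its own generative truth;
* log-linear exposure effects on a piecewise-constant attained-age baseline
  hazard; default band rates were set once so the default population's
  fatal event rate lands near 116 per 100,000 person-years (observed mean
  ≈ 112 across seeds at 20 × 2,000);
* entry ages from a truncated normal (mean 48, SD 12, support 20–85), 83.7%
  women, administrative censoring at 9 years, events labelled fatal with
  probability 0.54 — all matching the scale of the pooled LAC cohort
  population the package is designed around;
* two-layer missingness: whole variables unmeasured in a sampled subset of
  cohorts first (the dominant mechanism in consortium data), then
  within-cohort MCAR;
* exposure draws are normal truncated at physiologic floors (BMI > 10,
  SBP > 60, …) by resampling, keeping moments near-nominal while avoiding
  impossible values.

One master seed drives everything; internal stages (population, events,
measurement noise, missingness, fatal labels) use sub-streams at fixed
offsets from it, so reruns are reproducible stage by stage.

The generator deliberately does **not** emulate: correlation between risk
factors (no joint covariance), competing risks, time-varying usual levels
(no drift, no attenuation decay with measurement gap), cohort-specific
follow-up schedules, calendar time, or non-MCAR within-cohort missingness.
Passing tests on this synthetic population therefore demonstrate the
correctness of the estimators under their stated assumptions — not that
real cohort data satisfy those assumptions.

The fatal fraction by age is not separately specified; it is a single
Bernoulli probability (default 0.54) exposed as a knob, since no reliable
age profile was available to encode.

## Problem sizes and test design

The test suite and acceptance script run at desk scale by design: the
recovery study uses 100 replicates of 20 cohorts × 2,000 participants in a
single age band (Laplace approximation for speed; the adaptive-quadrature
default is exercised in the smaller fits), imputation tests use m ≤ 5, and
Monte Carlo intervals use a few hundred draws. These sizes were chosen as
the smallest at which the sampling tolerances in the tests are comfortably
binomial-stable, and they are stated here so they can be scaled up without
touching the machinery.

The packaged reference table of published sub-regional attributable-death
estimates carries integer death counts; premature-to-all-ages ratios
recomputed from those integers match the printed point percentages to
within 0.02 points, but the printed credible-bound ratios were evidently
computed from unrounded draws and can differ from integer arithmetic by up
to ~0.1 points — the tests pin the point estimates only.

## Known limitations

* Cohort enters the imputation model as fixed indicators, not random
  effects; under heavy cohort-level missingness the imputations borrow
  less between-cohort structure than a multilevel imputer would.
* The dilution factor is treated as fixed when correcting; its sampling
  error is not in the CIs.
* No joint multi-risk-factor PAF: attributable deaths are per risk factor
  and do not sum meaningfully across risk factors.
* The burden stage is a single-year snapshot; no time trends.
* No late entry other than baseline age, and no calendar-period dimension
  in the Lexis expansion.
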