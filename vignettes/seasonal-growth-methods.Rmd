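---
title: "Methods: seasonal growth faltering and the wasting-stunting relationship"
author: "wastunt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal growth faltering and the wasting-stunting relationship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wastunt)
```

## The scientific problem

Wasting (low weight-for-length, WLZ < -2) and stunting (low length-for-age,
LAZ < -2) are usually treated as separate forms of child undernutrition. In
strongly seasonal subsistence-farming environments — the package's motivating
setting is a rural West African community with a July–October "hungry"
(lean, wet) season — routine clinic growth monitoring yields dense
longitudinal anthropometry from which their interplay can be studied: does a
wasting episode raise the risk of becoming stunted a season later? Does
season of birth shape the growth trajectory? `wastunt` implements that whole
analysis chain as reusable, tested components:

1. **anthropometric z-scoring** against a pluggable LMS (Box–Cox) reference;
2. **cohort cleaning** with the standard implausible-z limits and an
   extreme between-visit change rule;
3. **cross-sectional prevalence** of wasting/stunting/concurrence by sex and
   completed month of age;
4. **seasonal episode analysis** over each infant's first wet season,
   intervening dry season and second wet season;
5. **mixed-effects growth curves** with cosinor (Fourier) seasonality and
   per-child seasonal amplitudes (the CCV);
6. **stunting-risk logistic models** and **time-lagged multilevel logistic
   models**;
7. a **seeded synthetic cohort generator** providing ground truth for every
   recovery and cleaning property.

## z-scores and classification

A measurement \(x\) with reference triple \((L, M, S)\) has
\[
  z = \frac{(x/M)^L - 1}{L\,S}, \qquad z \to \frac{\log(x/M)}{S}
  \text{ as } L \to 0 .
\]
We evaluate the numerator with `expm1` and invert with `log1p`, which keeps
the computation accurate to well below 1e-10 across the L→0 crossover (the
naive power form loses ~1e-8 there); the log form is used when |L| < 1e-7.
LAZ is indexed by age in days, WLZ by length in cm (recumbent-length
convention; the cohorts of interest are under two years). Reference tables
interpolate L, M and S linearly in the index, which is adequate at
day/centimetre granularity, and refuse out-of-range lookups rather than
extrapolating.

The bundled reference (`toy_lms_reference()`, also shipped as
`inst/extdata/toy_lms_reference.csv`) is **synthetic**: smooth analytic
curves with realistic magnitudes covering 0–26 months and 30–120 cm for both
sexes. Real WHO tables with the same schema
(`sex, axis, index_value, L, M, S`) are a drop-in replacement through
`read_lms_reference()`.

All thresholds are strict: wasted iff WLZ < -2, stunted iff LAZ < -2,
concurrent iff both, small MUAC iff MUAC < 12.5 cm. Missing inputs propagate
to missing flags; a flag is only ever FALSE when the measured value says so.

## Cleaning rules

Two visit-level rules run in a fixed order:

* **Implausible z-scores** (first): LAZ > 6, LAZ < -6, WLZ > 5 or WLZ < -5,
  all strict.
* **Extreme change** (second, on the already-filtered sequences): within a
  subject, any consecutive-visit change of more than 3 z-score units marks a
  pair; the pair member farther from that subject's median z is excluded
  (ties exclude the later visit) and the scan repeats until no violating
  pair remains. The rule is applied to LAZ and then to WLZ; a visit failing
  either is excluded entirely, with its reason recorded. Which outlying
  member of a violating pair to drop is not dictated by the rule's usual
  statement; distance-from-median was chosen because it is robust,
  deterministic and idempotent (re-cleaning cleaned data removes nothing —
  a tested property).

A participant whose visits are all excluded is counted as an excluded
participant, and the report enforces the conservation identity
input visits = output visits + per-rule exclusions.

Completed months of age are `floor(age_days / 30.4375)` (one month =
365.25/12 days) everywhere in the package.

## Prevalence and the 20–24-month outcome

When a subject contributes several measurements in one completed month, the
mean z-score within the month is classified, not the individual visits
(mean-then-classify). Prevalence per sex and month counts subjects, not
visits. The binary outcome "stunted at 20–24 months" defaults to mean LAZ
over visits at completed months 20–23 being below -2, mirroring the
within-month rule; an any-monthly-bin alternative is provided
(`rule = "any"`) because either reading is defensible. Subjects without
visits in the window are missing, and models using the outcome drop them.

An optional presentation smoother (local linear regression with tricube
weights, span 0.6) is provided for prevalence curves; nothing downstream
consumes it.

## Season windows and episodes

The wet season is July–October inclusive (month-level calendar rule; no
rainfall data). A child's first wet season is the wet window containing the
date of birth when born in July–October — the birth visit itself counts as
an observation, with a toggle — otherwise the first wet window after birth;
the second wet season is the following year's window and the intervening dry
season (1 November – 30 June) sits between. Per window, a subject's median
WLZ (midpoint convention for even counts) classifies the episode as wasted,
and a subject is eligible for the repeated-wasting model iff all three
windows contain at least one observation. That model is a plain logistic
regression of second-wet-season wasting on first-wet-season and dry-season
wasting, the dry-season term separating year-round from episodic wasting.

## The growth model

For one sex at a time, WLZ (or LAZ) is modelled by a linear mixed model

\[
  z_{ij} = f(a_{ij}) + \sum_{k=1}^{2}\big[\alpha_k \sin(k\omega t_{ij}) +
  \beta_k \cos(k\omega t_{ij})\big]
  + a_{ij}\big[\gamma_s \sin(\omega t_{ij}) + \gamma_c \cos(\omega t_{ij})\big]
  + u_{0i} + u_{1i} a_{ij} + a_i^{s} \sin(\omega t_{ij}) + b_i^{s}
  \cos(\omega t_{ij}) + \varepsilon_{ij}
\]

with \(a_{ij}\) the age in months, \(t_{ij}\) the day of year of the visit,
\(\omega = 2\pi/365.25\), and \(f\) a natural cubic spline (boundary knots 0
and 24 months; three interior knots at the 25th/50th/75th age percentiles by
default — the spline family needs a df choice and 5 df spans 0–24 months
without chasing noise; both are configurable). The linear-age × first-order
Fourier interaction is the parsimonious encoding of age-varying seasonal
amplitude. Estimation is REML via `lme4::lmer` with an unstructured 4×4
random-effect covariance; on failure the fit falls back to a diagonal
covariance and records that it did.

Day of year is the seasonal time variable, so trajectories are exactly
periodic in the birth date (up to leap-year re-indexing) and the Fourier
terms integrate to ~0 over a year, making the spline the aseasonal mean
curve.

Each child's seasonal random-effect pair \((a_i^s, b_i^s)\) is summarised by
the **coefficient of cyclic variation**,
\(\mathrm{CCV}_i = \sqrt{(a_i^s)^2 + (b_i^s)^2}\): the amplitude, in z-score
units, of that child's annual cycle over and above the population's seasonal
curve. The raw amplitude is used rather than an amplitude/mean ratio:
z-scores cross zero, so normalising by a mean is unstable. The definition is
isolated in `compute_ccv()` so an alternative can be swapped in.

Population trajectories for chosen birth dates (`predict_trajectory`) set
the random effects to zero; the stunted/non-stunted stratified fits
(`fit_by_outcome_group`) skip strata under 10 subjects with a warning.

## Risk models

`fit_logistic` wraps maximum-likelihood `glm` and reports odds ratios with
Wald 95% intervals, `exp(b ± 1.96 SE)` — chosen over profile likelihood for
symmetry and speed, with the internal consistency OR = exp(coef) tested to
1e-10. Quasi-complete separation aborts with the offending term named;
constant columns are dropped with a warning. The three nested stunting
models are I: sex + ever stunted; II: + ever wasted; III: + the growth-model
random effects (intercept, slope, CCV). "Ever" flags derive from the
monthly-bin classifications at completed months 0–19, keeping one canonical
classification pathway. All three models share one complete-case row set so
their log-likelihoods nest. In-sample classification diagnostics use a 0.5
probability threshold by default (configurable): error rate over everyone,
false-negative rate among the observed stunted, false-positive rate among
the observed non-stunted.

## Lagged analysis

Every visit is matched 1-to-1 to the same child's prior visit closest to 3
months earlier; candidates outside 2.5–3.5 months (at 30.4375 days/month)
are ignored and unmatched visits are dropped. An exact tie in closeness is
broken toward the longer lag (deterministic; either choice is defensible).
Matching operates on raw visits, not month bins, because the window is
expressed in days; flags come from the visit's own z-scores. The matcher is
verified against brute-force enumeration.

The lagged models are logistic mixed models (current stunting — or wasting —
on sex, lagged age in months, lagged stunting, lagged wasting) with a
subject random intercept, fitted by Laplace approximation (`lme4::glmer`,
`nAGQ` configurable; a hard failure falls back to `nAGQ = 0` with a
warning). No interaction terms are included. Scenario probabilities
(`predict_scenarios`) are population-level inverse-logit values over the
sex × lagged-state × lagged-age grid, labelled by the four lagged-state
groups.

## The synthetic cohort generator

Validation needs data with known truth; clinic records of this kind are not
publicly deposited. The generator emulates their structure under one
default configuration chosen up front:

* births uniform over 1990–1993 (all calendar months, which de-aliases age
  from season); visits at birth, 6 weeks, 3 months, then 3-monthly to 24
  months; 90% attendance (95% at birth) and ±7-day (truncated ±21) date
  jitter — median 9 visits per child;
* LAZ mean declining linearly from -0.45 at birth to -1.45 at 24 months;
  WLZ mean with early catch-up (-0.55 at birth to +0.05 at 2.5 months) then
  decline to -0.9 at 12 months and partial recovery; boys 0.12 / 0.08 z
  worse;
* seasonal forcing of WLZ with amplitude 0.4 z peaking (as a deficit) on day
  258 (mid-September, late wet season), amplitude growing mildly with age;
  LAZ forcing of 0.15 z delayed by 90 days, so the length cycle lags the
  weight cycle — a recoverable structure;
* random effects: intercept SD 0.55, slope SD 0.02/month, seasonal pair SD
  0.5 per component, residual SD 0.6 for WLZ (0.9 / 0.03 / 0.45 for LAZ).
  The seasonal-pair and residual SDs encode a setting where individual
  seasonal susceptibility is of the same order as the population cycle and
  measurement-plus-short-term noise is moderate;
* lagged coupling: each prior wasted visit deepens the child's LAZ by
  0.18 z, accumulating over at most 3 episodes — wasting leaves a permanent
  mark on linear growth;
* optional planted outliers: implausible z-scores beyond the ±6/±5 limits
  and single-visit spikes engineered to violate the 3-SD change rule while
  staying inside the implausible bounds (spikes landing near a child's
  median are intentionally hard, hence the 95% rather than 100% recall
  bar).

Raw length and weight are back-computed through the LMS reference, so the
whole z-score pathway is exercised end-to-end, and a truth manifest records
every random effect, noiseless z-score and planted corruption. A second,
deliberately separate pathway (`generate_binary_panel`) simulates 3-monthly
binary (stunted, wasted) Markov chains from a logistic transition model with
subject random intercepts and known log-odds — transition defaults echo the
magnitudes reported for this kind of cohort (wasting→stunting ln 3.2, boys
ln 1.6, age ln 1.1/month, persistence ln 8.2) — for coefficient-recovery
testing of the lagged models. The two pathways are not forced to be mutually
consistent. Everything is reproducible bit-for-bit from the configuration
seed.

What the generator does **not** emulate: mortality and migration, secular
trends across decades, informative missingness, measurement digit
preference, twins/family clustering. Passing recovery tests therefore shows
the estimators work when their assumptions hold (plus planted violations),
not that real records meet those assumptions.

## Numerical and design notes

* **Problem sizes.** The validation suite uses cohorts of 200–1,000 children
  and panels of 1,000–4,000; these sizes give each check enough power for
  its stated bound (e.g. the conditional ever-wasted OR of ~1.4 needs
  roughly 1,000 subjects to be directionally stable) while keeping a full
  run in minutes.
* **Amplitude recovery** is assessed under age-constant forcing
  (`amp_age_slope = 0`); with age-varying forcing there is no single true
  amplitude to compare against, and the annual-harmonic fixed-effect pair
  estimates the age-zero amplitude.
* **Dynamic-panel endogeneity.** In the lagged models, the lagged *own*
  state is by construction correlated with the subject's random intercept,
  so its coefficient absorbs part of the subject heterogeneity and its null
  intervals undercover slightly (~88% observed; the effect persists under
  high-order adaptive quadrature, so it is not an integration artifact).
  The cross-lagged coefficients — the substantive quantities — are
  well-calibrated (~93% coverage under a full null). Persistence ORs should
  accordingly be read as descriptive.
* **Boundary variance estimates.** When the true random-intercept variance
  is 0, its estimate has half-normal sampling noise; fixed effects coincide
  with plain logistic regression only as the estimate reaches the boundary.
* **REML optimisation** of the 4-dimensional unstructured random-effect
  covariance has a flat likelihood along correlation directions in small
  samples: row order can perturb coefficients by ~1e-3 z. Fits are exactly
  reproducible for identical input.
* **Degenerate inputs**: empty design frames, out-of-range LMS lookups,
  all-constant predictors, separated logistic fits, strata under 10
  subjects and panels under 100 pairs all fail or warn explicitly rather
  than silently.

## Limitations

The package consumes LMS tables and does not construct growth standards;
MUAC enters only as a classification flag; no imputation (records are
dropped, as in the motivating analyses); diagnostics are in-sample; and the
season calendar is purely calendrical. Formal inference comparing stratified
growth curves is deliberately out of scope — the stratified fits are
descriptive.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_subjects = 300, outlier_rate = 0.01, seed = 1)
res <- run_pipeline(config = cfg, output_dir = "artifacts")
res$cleaning$report
res$lag$stunting
```
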