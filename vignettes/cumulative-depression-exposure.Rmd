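---
title: "Cumulative depression-symptom exposure and dementia risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative depression-symptom exposure and dementia risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumdep)
```

# The analytic problem

Aging panel studies measure depressive symptoms repeatedly — typically three
biennial waves of a bounded self-report scale — and then follow participants
for incident dementia. A single baseline measurement cannot distinguish a
transient low mood from a decade of sustained burden, nor a stable moderate
score from a highly unstable one. `cumdep` operationalizes the longitudinal
alternatives: cumulative exposure, exposure duration, trajectory, and
visit-to-visit variability, each feeding a proportional-hazards analysis of
time to dementia.

# Exposure constructs

## Cumulative score and cumulative average

For scores $S_1,\dots,S_W$ at times $t_1 < \dots < t_W$ (years since the
first visit), the cumulative score is the trapezoid integral

$$\mathrm{CumDS} = \sum_{i=1}^{W-1} \frac{S_i + S_{i+1}}{2}\,(t_{i+1}-t_i)$$

in score-years, i.e. the exact integral of the piecewise-linear
interpolation of the trajectory. It is additive under interval splitting
(inserting an interpolated midpoint changes nothing, a property the tests
verify to 1e-10) and monotone in each score. The cumulative average
$\mathrm{CumADS} = \mathrm{CumDS}/(t_W-t_1)$ is a time-weighted mean score,
bounded by the observed score range and invariant to the time unit.

## Burden, duration, slope, pattern

*Cumulative burden* centers CumDS on a cutoff $c$:
$\mathrm{CumDS} - c\,(t_W - t_1)$, an algebraic identity with the trapezoid
integral of $S-c$. The sign dichotomizes sustained exposure; the boundary
value 0 is classed as non-negative, matching the "< 0 vs ≥ 0" presentation
convention. Which $c$ to use is genuinely open — the screening threshold or
the outcome-oriented cutoff below — so the centering constant is an explicit
argument; the pipeline defaults to the same cutoff it uses for duration.

*Exposure duration* counts high-score visits ($S \ge c$, boundary
inclusive) inside a designated two-visit window and converts the count to
0/2/4 years at the biennial cadence. Which two of the three visits form the
window is not dictated by the construct; the package defaults to waves 1–2
(the earliest window, maximizing subsequent follow-up) and records the
window in output metadata, with waves configurable.

*Slope* is the per-participant OLS slope of score on time; its sign defines
the binary progression strata. The *time-course pattern* classifies the two
successive changes of a three-wave trajectory into four categories. A zero
change maps to "decrease": the four-category scheme has no stable class, and
non-increase is the conservative assignment, applied identically to both
transitions so the classifier is exhaustive and mutually exclusive over all
integer score triples (verified by enumeration in the tests).

## Quartiles and the trend test

Cohort-level quartiles use the linear-interpolation quantile rule (R type
7), the most common and platform-reproducible default; values tying a
breakpoint fall to the lower quartile. The dose-response trend test follows
the quartile-median convention: each participant's quartile label is
replaced by the quartile's median exposure value and the Cox model is refit
with this single continuous term, whose Wald p is the trend p.

## Visit-to-visit variability

Per-person dispersion uses the sample SD ($n-1$ denominator — conventional
for few visits and stated so results are reproducible), CV = SD/mean
(undefined at mean 0), and VIM:

$$\mathrm{VIM} = 100 \times \mathrm{SD} / \mathrm{mean}^{\beta},$$

where $\beta$ is the cohort-level OLS slope of $\ln \mathrm{SD}$ on
$\ln \mathrm{mean}$. By construction the OLS slope of
$\ln \mathrm{VIM}$ on $\ln \mathrm{mean}$ over the calibration sample is
exactly zero (the tests check to 1e-8), and $\beta = 1$ or $0$ collapse VIM
to $100\,\mathrm{CV}$ or $100\,\mathrm{SD}$. Participants with zero SD or
non-positive mean cannot enter the log-log fit: they are excluded from
calibration with counts recorded, keep their SD (and CV where defined), and
receive no VIM. Calibration is per cohort, since the instruments' scales
differ; pooling cohorts before calibration would let the cohort means drive
$\beta$.

# Outcome-oriented cutoff

The high-symptom cutoff can be taken from the instrument's screening
threshold, fixed by hand, or searched: evaluate the two-sample log-rank
statistic at every distinct observed score $c$ such that the split
"$S \ge c$" leaves each group at least 10% of the sample (the usual guard
against degenerate extreme splits in maximally selected statistics;
configurable), and keep the maximizer, breaking ties toward the smaller
cutoff for determinism. The log-rank statistic itself is implemented in the
package (observed minus expected events over risk sets with hypergeometric
covariance, generalized to $k$ groups) and is cross-checked against an
independent implementation in the tests. No selection-adjusted p-value is
computed: the cutoff defines exposure strata and is never itself reported
as a test. The search pools per-visit scores over the exposure waves by
default (a baseline-only search is a configuration choice), since the
duration construct applies the cutoff to individual visits.

# Algorithmic dementia ascertainment

Cognition norms are means and sample SDs of baseline-wave domain scores per
education stratum — baseline only, so incident decline does not contaminate
the reference distribution. Cognitive impairment is any domain at or below
mean − 1.5 SD (boundary inclusive). Functional impairment is ≥ 1 ADL
difficulty. The concurrence rule requires both at the same wave; the
summary-score rule instead cuts a 0–27 memory + executive composite at ≤ 6.
A self-reported physician diagnosis confers positivity under the "either"
basis. Classification is absorbing: once positive, positive at all later
waves, so `first_positive_wave` is well defined. The lagged analysis drops
participants first positive at wave 2 — the incident cases closest to
baseline, most plausibly prodromal — and refits; the event count falls by
exactly the number excluded.

# Survival modelling

The covariate ladder is M1 (unadjusted), M2 (+ age, gender, marital status,
education, residence), M3 (+ smoking, drinking, CRP, HbA1c, TC, HDL-C), and
M4 (+ hypertension, diabetes, heart disease, stroke); the sets are strictly
nested, so partial likelihood is non-decreasing along the ladder on common
rows. Fits use Efron tie handling by default (Breslow by flag), follow-up
time from baseline, Wald CIs on the log scale with $z = 1.96$. Follow-up
time from the exposure-window end is available as a landmark option for
users concerned about immortal time when exposure spans the waves;
the default mirrors the baseline-origin convention of the emulated designs
and is stamped into output metadata. Non-convergence raises an error;
possible infinite coefficients (separation) raise a warning and flag the
fit. A proportional-hazards diagnostic is deliberately not a gate on
results.

Restricted cubic splines use the truncated-power natural-spline basis
(first column linear, $k-2$ nonlinear columns normalized by the squared
knot span) with knots at the standard quantile recipes — 10/50/90% for 3
knots, 5/35/65/95% for 4, 5/27.5/50/72.5/95% for 5 — and the knot count
chosen by minimum BIC, computed as $-2\,\ell + p \ln(\text{events})$ with
$p$ the number of fitted coefficients. The separable basis is what makes
`p_nonlinear` a clean Wald test of the nonlinear columns only; `p_overall`
tests all spline terms. Curves are reported as log hazard ratios relative
to the cohort median of the exposure (a reference must be chosen; the
median is stable and scale-free) with delta-method pointwise CIs.

Cross-cohort pooling of per-SD effects stacks within-cohort z-standardized
exposures and fits a cohort-stratified Cox model (separate baseline hazards
per cohort, one common coefficient). Logistic sensitivity analyses refit
the ladder on the binary ever-dementia outcome with complete cases only,
reporting odds ratios; with incidence well under 10% these approximate the
hazard ratios (the rare-disease check in the tests).

# The synthetic cohort generator

The generator exists so that every downstream stage has a testable ground
truth. It emulates the structure the analysis assumes:

- **Trajectories.** Score at wave $w$: person intercept + person slope
  × time + visit noise, rounded half-away-from-zero (keeps marginal means
  unbiased near mid-scale) and clipped to the scale range. Three biennial
  waves by default. Per-scale defaults (CES-D-8: intercept 1.0 ± 1.5,
  slope 0.05 ± 0.25/yr, noise SD 0.9; EURO-D: intercept 2.3 ± 1.5;
  CES-D-10: intercept 7.5 ± 4.0, slope 0.10 ± 0.60/yr, noise SD 2.0) are
  chosen once so the marginal screening-positive prevalence lands in the
  18–32% band reported for these instruments in population panels.
- **Covariates.** Drawn independently with marginals resembling pooled
  aging-cohort tables (55% female, 70% married, three education strata,
  ~44% hypertension, lognormal CRP, and so on). Independence is a deliberate
  simplification: it suffices for parameter-recovery testing, which is the
  generator's purpose.
- **Events.** Exposure metrics are derived from the generated trajectories
  with the package's own formulas and entered as baseline-fixed covariates
  in an exponential-baseline proportional-hazards model; event times are
  drawn from that model and censored administratively at 10.8 years (the
  pooled median follow-up of the emulated designs). Exposure terms are
  mean-centered inside the linear predictor so that the marginal incidence
  (~12%/decade at the default baseline hazard of 0.012/yr, a realistic
  algorithmic-dementia incidence for 50+ cohorts) does not drift with the
  chosen effect size; centering is absorbed by the baseline hazard and does
  not alter fitted coefficients. Configurations in which > 99% of subjects
  fail inside the exposure window are rejected as degenerate.
- **Cognition/ADL.** For classifier testing, event participants receive,
  from their event wave onward, a memory score 2.5 SD below their stratum's
  generating mean plus ≥ 1 ADL difficulty (or a composite ≤ 6 under the
  summary rule); non-events are drawn truncated above 1.4 SD below the
  mean. With zero noise, classification against the generating norms
  recovers the planted outcome exactly — the sensitivity/specificity-1
  tests rely on this construction, and the distinction between generating
  norms and empirically re-estimated norms is intentional.

What passing tests therefore show: the estimators recover known effects
from data satisfying the model's assumptions. What they do not show:
robustness to informative dropout, correlated covariates, measurement
error in cognition, culturally differential reporting, or misspecified
hazards — features of real cohort data the generator deliberately omits.

# Numerical and design choices

- Rounding: half-away-from-zero before clipping (symmetric around zero,
  unbiased at mid-scale).
- Quantiles: R type 7 everywhere (quartiles, spline knots).
- Ties: at the cutoff, high group; at quartile breakpoints, lower quartile;
  at equal log-rank statistics, smaller cutoff; Cox ties, Efron.
- Zero change in the pattern classifier: "decrease" (see above).
- Missing scores: participants lacking any wave score are excluded before
  metric computation; no within-pipeline imputation (multi-wave imputation
  belongs upstream of this package).
- Exclusion cascade order: missing sociodemographics → below age threshold
  → prevalent dementia → loss to follow-up → incomplete assessments, with
  per-step counts reported; age thresholds configurable per cohort preset
  (50 for ELSA/HRS-style, 45 for SHARE/CHARLS-style).
- Norms are computed after the sociodemographic/age exclusions and before
  the outcome-dependent ones.

# Problem sizes in the test suite

The property suites run at the sizes where each property is informative and
the suite stays quick: exhaustive enumeration for the pattern classifier
(729 triples), n = 1000 for the VIM exponent recovery (±0.05), 100 small
datasets (n ≤ 50) for the cutpoint brute-force oracle, 200 replicates of
n = 500 for null calibration of the Wald and trend tests, 20 replicates of
n = 5000 for effect recovery at published effect sizes, and 100 + 50
replicates of n = 4000 for the spline level/power checks. These are the
package's chosen test conditions, stated here so they can be scaled by
users with different precision needs.

# Known limitations

- The generator's covariates carry no confounding structure by default, so
  adjusted and unadjusted fits estimate the same quantity in simulation;
  confounding scenarios require user-specified covariate effects.
- VIM calibration excludes zero-SD participants, so cohorts with very flat
  trajectories calibrate on a selected subsample.
- The maximally selected cutoff is reported without a selection-adjusted
  significance level; treating the maximized statistic as a fixed-cutoff
  test would be anti-conservative.
- Very sparse extreme exposure strata produce large, unstable hazard
  ratios; the Kaplan-Meier output exists precisely to contextualize such
  estimates with absolute incidence.
- Delayed-entry (age-scale) analyses are supported only through the
  landmark option, not through full left-truncation machinery.
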