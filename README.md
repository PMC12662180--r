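# cumdep

Longitudinal depression-symptom exposure and incident dementia in aging
panel cohorts.

Single-visit depression measurements miss what repeated-measures panels can
see: how much symptom burden accumulates, how long it stays high, which way
it is heading, and how much it fluctuates. `cumdep` is an R package for
epidemiologists analyzing cohorts of the ELSA / HRS / SHARE / CHARLS type —
three (or more) biennial waves of a bounded symptom scale (CES-D-8, 0–8;
CES-D-10, 0–30; EURO-D, 0–12) followed by dementia surveillance — who want
the full battery of longitudinal exposure constructs and the survival
models around them, plus a synthetic-cohort generator with known ground
truth so every stage is testable without restricted cohort data.

## What it computes

**Exposure metrics** (per participant, from scores S₁…S_W at times
t₁…t_W):

- Cumulative score (CumDS), the trapezoid integral
  Σᵢ ((Sᵢ + Sᵢ₊₁)/2)(tᵢ₊₁ − tᵢ) in score-years; cumulative average
  (CumADS) = CumDS / (t_W − t₁).
- Cumulative burden = CumDS − c(t_W − t₁) for a cutoff c, dichotomized at 0
  (boundary inclusive).
- High-symptom exposure duration: 2 years per visit with score ≥ c within a
  two-visit window (0/2/4 years).
- OLS slope of score on time, and the four-way time-course pattern
  (decrease/increase × decrease/increase; Δ = 0 counts as decrease).
- Visit-to-visit variability: SD, CV = SD/mean, and VIM = 100·SD/meanᵝ,
  with β the cohort-level OLS slope of ln SD on ln mean.

**Outcome machinery**:

- Outcome-oriented dichotomization: the score cutoff maximizing the
  two-sample log-rank statistic over a candidate grid (ties at the cutoff
  go high; minimum group fraction guards extreme splits).
- Harmonized algorithmic dementia: any cognitive domain ≥ 1.5 SD below its
  education-stratified norm *and* ≥ 1 ADL difficulty (concurrence rule), or
  a 0–27 cognition composite ≤ 6 (HRS-style summary rule), optionally
  combined with self-reported physician diagnosis; classification is
  absorbing across waves.

**Inference** (all via `survival::coxph` under the hood): the nested
covariate ladder M1–M4 (unadjusted → sociodemographics → lifestyle + labs →
comorbidities) on every exposure coding, quartile trend tests via quartile
medians, BIC-selected restricted cubic splines with linear/nonlinear Wald
tests, Kaplan–Meier curves with a k-group log-rank test, subgroup
interaction tests, within-cohort z-standardization, lagged analyses
excluding wave-2 incident cases, and complete-case logistic sensitivity
models.

## Worked example

```r
library(cumdep)

cfg    <- sim_config(2000, scale = "CESD8",
                     betas = list(cumds = log(1.06)), seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> <dep_cohort> 2000 participants, 3 waves (CESD8), 238 events (11.9%)

dat <- merge(cohort$participants,
             derive_exposures(cohort, cutoff = 3), by = "id")
fit <- fit_cox(dat, "cumds", model = "M4")
fit$table[fit$table$term == "cumds", ]
#>   term  coef     se   hr   lo   hi        p
#>  cumds 0.063 0.0112 1.07 1.04 1.09 1.86e-08

q <- assign_quartiles(dat$cumds)
trend_test(dat, q, model = "M4")$p
#> 1.6e-07

attr(add_variability(cohort), "calibration")
#> <vim_calibration> beta = 0.2012 (intercept -0.2239), n used = 1484, excluded = 516
```

The cohort was generated with a true per-unit hazard ratio of 1.06 on the
cumulative score; the fully adjusted fit returns HR 1.07 (95% CI
1.04–1.09), covering the truth, and the quartile-median trend test confirms
the monotone dose–response. The VIM calibration exponent (β ≈ 0.20) is the
fitted log-log slope of per-person SD on per-person mean for this cohort;
516 participants with zero SD or zero mean receive SD/CV but no VIM.

A full end-to-end run (simulate → classify → validate → exposures → VIM →
cutoff → model ladder → KM → splines, with CSV artifacts and run metadata)
is one call:

```r
out <- run_pipeline(list(
  simulation = list(n_participants = 2000, scale = "CESD8",
                    betas = list(cumds = log(1.06)), seed = 1),
  cutoff_source = "search", models = c("M1", "M4"),
  outdir = "reports"))
```

or from a shell via `inst/scripts/cumdep-pipeline.R --config demo.yaml`.

## Package layout

- `R/` — scales, synthetic cohort generator, exposure metrics, variability
  + VIM, cutpoint search, dementia classifier, Cox/spline/KM ladder,
  pipeline.
- `tests/testthat/` — unit, property and end-to-end recovery suites.
- `vignettes/cumulative-depression-exposure.Rmd` — the methods vignette:
  model, assumptions, parameter choices, design decisions, limitations.
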