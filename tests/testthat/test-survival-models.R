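test_that("Cox score test equals the two-sample log-rank statistic", {
  set.seed(91)
  n <- 80
  g <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.4 * g))   # continuous times: no ties
  event <- as.integer(time < 15); time <- pmin(time, 15)
  d <- data.frame(time_years = time, event = event, g = g)
  f <- fit_cox(d, "g", model = "M1")
  lr <- logrank_statistic(time, event, g)
  expect_equal(f$score, lr, tolerance = 1e-6)
})

test_that("two-group exponential data recover the true rate ratio 2", {
  set.seed(92)
  n <- 4000
  g <- rep(0:1, each = n / 2)
  d <- data.frame(time_years = rexp(n, 0.1 * 2^g), event = 1L, g = g)
  f <- fit_cox(d, "g", model = "M1")
  expect_equal(f$table$hr[1], 2, tolerance = 0.1)
})

test_that("landmark origin drops pre-landmark follow-up and restarts the clock", {
  co <- quick_cohort(n = 2000, seed = 25, betas = list(cumds = log(1.08)))
  d <- cohort_data(co)
  f <- fit_cox(d, "cumds", model = "M1", time_origin = "exposure_end",
               landmark_years = 4)
  expect_equal(f$n, sum(d$time_years > 4))
  expect_equal(f$events, sum(d$event[d$time_years > 4]))
  expect_lt(f$events, sum(d$event))
  # effect estimate remains in the neighborhood of the truth
  expect_equal(f$table$coef[f$table$term == "cumds"], log(1.08),
               tolerance = 0.5)
})

test_that("constant exposure and zero events are rejected", {
  d <- data.frame(time_years = rexp(50) + 0.1, event = 1L, x = 1)
  expect_error(fit_cox(d, "x", model = "M1"), "constant")
  d2 <- data.frame(time_years = rexp(50) + 0.1, event = 0L, x = rnorm(50))
  expect_error(fit_cox(d2, "x", model = "M1"), "zero events")
})

test_that("model ladder is nested and deviance non-increasing M1 -> M4", {
  co <- quick_cohort(n = 2000, seed = 14, betas = list(cumds = log(1.08)))
  d <- cohort_data(co)
  expect_true(all(model_covariates("M2") %in% model_covariates("M3")))
  expect_true(all(model_covariates("M3") %in% model_covariates("M4")))
  expect_length(model_covariates("M1"), 0)
  lls <- vapply(c("M1", "M2", "M3", "M4"), function(m)
    fit_cox(d, "cumds", model = m)$loglik, numeric(1))
  expect_true(all(diff(lls) > -1e-8))   # adding covariates never hurts fit
})

test_that("hazard ratios and CIs follow the Wald construction", {
  co <- quick_cohort(n = 1500, seed = 15, betas = list(cumds = log(1.1)))
  d <- cohort_data(co)
  f <- fit_cox(d, "cumds", model = "M2")
  row <- f$table[f$table$term == "cumds", ]
  expect_equal(row$hr, exp(row$coef))
  expect_equal(row$lo, exp(row$coef - 1.96 * row$se))
  expect_equal(row$hi, exp(row$coef + 1.96 * row$se))
})

test_that("quartile trend test maps quartile medians row by row and detects monotone effects", {
  co <- quick_cohort(n = 4000, seed = 16, betas = list(cumds = log(1.08)))
  d <- cohort_data(co)
  q <- assign_quartiles(d$cumds)
  tt <- trend_test(d, q, model = "M1")
  expect_lt(tt$p, 0.001)
  # mapping bookkeeping
  expect_equal(tt$fit$fit$n, nrow(d))
  mapped <- q$medians[q$labels]
  expect_equal(sort(unique(mapped)), sort(q$medians))
  expect_true(all(mapped[q$labels == 2] == q$medians[2]))
})

test_that("KM product-limit matches hand computation and empirical survival", {
  # times 1, 2+ (censored), 3: S(1) = 2/3, S(3) = 0
  d <- data.frame(time_years = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_estimate(d, rep("all", 3))
  s1 <- km$table$surv[km$table$time == 1]
  s3 <- km$table$surv[km$table$time == 3]
  expect_equal(s1, 2 / 3); expect_equal(s3, 0)
  # no events: survival identically 1
  d2 <- data.frame(time_years = 1:5, event = 0L)
  km2 <- km_estimate(d2, rep("all", 5))
  expect_true(all(km2$table$surv == 1))
  # with no censoring the KM estimate is the empirical survival function
  set.seed(17)
  t3 <- rexp(100)
  d3 <- data.frame(time_years = t3, event = 1L)
  km3 <- km_estimate(d3, rep("all", 100))
  emp <- vapply(km3$table$time, function(u) mean(t3 > u), numeric(1))
  expect_equal(km3$table$surv, emp, tolerance = 1e-12)
})

test_that("ordered quartile hazards give ordered KM curves and a decisive log-rank", {
  co <- quick_cohort(n = 4000, seed = 18, betas = list(cumds = log(1.12)))
  d <- cohort_data(co)
  q <- assign_quartiles(d$cumds)
  km <- km_estimate(d, q$labels)
  expect_lt(km$logrank$p, 0.001)
  final <- vapply(as.character(1:4), function(g) {
    tb <- km$table[km$table$group == g, ]
    tb$surv[which.max(tb$time)]
  }, numeric(1))
  expect_true(all(diff(final) < 0))  # higher quartile, lower survival
})

test_that("z-standardization gives unit variance per cohort and the per-SD HR identity", {
  expect_equal(zstandardize(c(2, 4, 6)), c(-1, 0, 1))
  x <- c(rnorm(50, 5, 2), rnorm(50, 20, 7))
  g <- rep(1:2, each = 50)
  z <- zstandardize(x, g)
  for (k in 1:2) {
    expect_equal(mean(z[g == k]), 0, tolerance = 1e-12)
    expect_equal(sd(z[g == k]), 1, tolerance = 1e-12)
  }
  expect_error(zstandardize(rep(3, 10)), "zero SD")
  # HR per 1 SD equals the per-unit HR raised to the SD
  co <- quick_cohort(n = 3000, seed = 19, betas = list(cumds = log(1.08)))
  d <- cohort_data(co)
  d$z <- zstandardize(d$cumds)
  f1 <- fit_cox(d, "cumds", model = "M1")
  fz <- fit_cox(d, "z", model = "M1")
  expect_equal(fz$table$coef[1], f1$table$coef[1] * sd(d$cumds),
               tolerance = 1e-6)
})

test_that("subgroup analysis returns per-stratum fits and a calibrated interaction test", {
  co <- quick_cohort(n = 3000, seed = 20, betas = list(cumds = log(1.08)))
  d <- cohort_data(co)
  sg <- subgroup_analysis(d, "cumds", "gender", model = "M2")
  expect_named(sg$strata, c("Male", "Female"))
  expect_s3_class(sg$strata$Male, "dep_coxfit")
  expect_true(sg$interaction_p > 0 && sg$interaction_p <= 1)
  # homogeneous truth: interaction rarely significant
  ps <- vapply(1:15, function(r) {
    cc <- quick_cohort(n = 1200, seed = 300 + r, betas = list(cumds = log(1.06)))
    dd <- cohort_data(cc)
    subgroup_analysis(dd, "cumds", "gender", model = "M1")$interaction_p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.3)
})

test_that("logistic sensitivity approximates the HR for a rare outcome and logs complete cases", {
  co <- quick_cohort(n = 5000, seed = 21, betas = list(cumds = log(1.06)),
                     baseline_hazard = 0.004)   # ~4% incidence
  d <- cohort_data(co)
  ls <- logistic_sensitivity(d, "cumds", model = "M1")
  or <- ls$table$or[ls$table$term == "cumds"]
  f <- fit_cox(d, "cumds", model = "M1")
  expect_equal(or, f$table$hr[1], tolerance = 0.1)   # rare-disease closeness
  # complete-case bookkeeping
  d$crp[1:25] <- NA
  ls2 <- logistic_sensitivity(d, "cumds", model = "M4")
  expect_equal(ls2$n_dropped, 25L)
  expect_equal(ls2$n, nrow(d) - 25L)
})

test_that("restricted spline basis is linear beyond the boundary knots", {
  kn <- c(2, 5, 8)
  x <- seq(-5, 15, by = 0.25)
  B <- rcs_basis(x, kn)
  # below the first knot all nonlinear terms vanish
  expect_true(all(B[x <= 2, 2] == 0))
  # beyond the last knot the curve is linear: second differences of any
  # fitted combination vanish
  tail_region <- x >= 8
  for (w in list(c(1, 1), c(0.5, -2))) {
    yhat <- B[tail_region, ] %*% w
    expect_equal(max(abs(diff(diff(yhat)))), 0, tolerance = 1e-9)
  }
  expect_error(rcs_basis(x, c(1, 2)), "3 knots")
})

test_that("spline fit under a linear log-hazard keeps the nonlinear terms at zero", {
  co <- quick_cohort(n = 4000, seed = 22, betas = list(cumads = log(1.35)))
  d <- cohort_data(co)
  sf <- rcs_fit(d, "cumads", model = "M1", candidate_knots = 3)
  expect_equal(sf$chosen_k, 3L)
  expect_gt(sf$p_nonlinear, 0.01)
  # the linear slope is recovered within Monte-Carlo error
  slope_region <- sf$curve$exposure > sf$knots[1] & sf$curve$exposure < sf$knots[3]
  fitted_slope <- coef(lm(loghr ~ exposure, data = sf$curve[slope_region, ]))[2]
  expect_equal(unname(fitted_slope), log(1.35), tolerance = 0.12)
})

test_that("BIC selection prefers fewer knots under linearity and the curve is anchored at the reference", {
  co <- quick_cohort(n = 3000, seed = 23, betas = list(cumads = log(1.3)))
  d <- cohort_data(co)
  sf <- rcs_fit(d, "cumads", model = "M1")
  expect_equal(unname(sf$bic[as.character(sf$chosen_k)]), min(sf$bic))
  ref_idx <- which.min(abs(sf$curve$exposure - sf$ref))
  expect_lt(abs(sf$curve$loghr[ref_idx]), 0.05)
  expect_error(rcs_fit(d[1:40, ], "event", model = "M1"), "distinct")
})

test_that("lagged exclusion then refit reproduces the pipeline on the reduced sample", {
  co <- quick_cohort(n = 4000, seed = 24, betas = list(cumds = log(1.08)))
  co <- simulate_cognition_adl(co)
  cls <- classify_dementia(co$panel, co$participants, norms = co$norms)
  d <- cohort_data(co)
  d$first_positive_wave <- cls$first_positive_wave[match(d$id, cls$id)]
  n_wave2 <- sum(d$first_positive_wave == 2, na.rm = TRUE)
  expect_gt(n_wave2, 0)
  lag <- lagged_exclusion(d)
  expect_equal(nrow(lag), nrow(d) - n_wave2)
  expect_equal(sum(lag$event) ,
               sum(d$event) - sum(d$event[which(d$first_positive_wave == 2)]))
  f <- fit_cox(lag, "cumds", model = "M4")
  expect_equal(f$n, nrow(lag))
  row <- f$table[f$table$term == "cumds", ]
  expect_equal(row$coef, log(1.08), tolerance = 0.35)
})
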