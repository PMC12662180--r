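test_that("cumulative score matches the trapezoid rule on worked examples", {
  expect_equal(cumulative_score(c(2, 4, 6), c(0, 2, 4)), 16)
  expect_equal(cumulative_score(c(0, 8), c(0, 2)), 8)
  # constant trajectory integrates to c * T whatever the time grid
  expect_equal(cumulative_score(c(5, 5, 5), c(0, 1.3, 4)), 5 * 4)
  expect_error(cumulative_score(c(1, 2), c(2, 2)), "increasing")
  expect_error(cumulative_score(3, 0), "waves")
  expect_error(cumulative_score(c(1, NA, 2), c(0, 1, 2)), "missing")
})

test_that("inserting an interpolated midpoint leaves the integral unchanged", {
  set.seed(42)
  for (rep in 1:25) {
    times <- sort(runif(4, 0, 10))
    while (any(diff(times) < 1e-3)) times <- sort(runif(4, 0, 10))
    scores <- runif(4, 0, 8)
    i <- sample(3, 1)
    tmid <- mean(times[c(i, i + 1)])
    smid <- approx(times, scores, xout = tmid)$y
    t2 <- append(times, tmid, after = i)
    s2 <- append(scores, smid, after = i)
    expect_equal(cumulative_score(s2, t2), cumulative_score(scores, times),
                 tolerance = 1e-10)
  }
})

test_that("cumulative average is the time-weighted mean, bounded by the scores", {
  expect_equal(cumulative_average(c(2, 4, 6), c(0, 2, 4)), 4)
  expect_equal(cumulative_average(c(0, 8), c(0, 2)), 4)
  # unit invariance: same value in months or years
  expect_equal(cumulative_average(c(3, 3, 3), c(0, 24, 48)), 3)
  set.seed(7)
  for (rep in 1:25) {
    s <- runif(3, 0, 8); tt <- cumsum(c(0, runif(2, 0.5, 3)))
    a <- cumulative_average(s, tt)
    expect_gte(a, min(s)); expect_lte(a, max(s))
  }
})

test_that("burden equals cumds minus cutoff times window length, boundary inclusive", {
  b <- cumulative_burden(c(2, 4, 6), c(0, 2, 4), cutoff = 3)
  expect_equal(b$burden_value, 4)
  expect_equal(b$burden_class, "nonnegative")
  b0 <- cumulative_burden(c(3, 3, 3), c(0, 2, 4), cutoff = 3)
  expect_equal(b0$burden_value, 0)
  expect_equal(b0$burden_class, "nonnegative")
  bn <- cumulative_burden(c(0, 0, 0), c(0, 2, 4), cutoff = 3)
  expect_equal(bn$burden_value, -12)
  expect_equal(bn$burden_class, "negative")
  set.seed(11)
  for (rep in 1:25) {
    s <- runif(3, 0, 8); tt <- cumsum(c(0, runif(2, 0.5, 3))); cut <- runif(1, 0, 8)
    expect_equal(cumulative_burden(s, tt, cut)$burden_value,
                 cumulative_score(s, tt) - cut * (tt[3] - tt[1]))
  }
})

test_that("exposure duration counts high visits in the two-wave window", {
  expect_equal(exposure_duration(c(5, 5, 0), cutoff = 3), 4)
  expect_equal(exposure_duration(c(1, 5, 0), cutoff = 3), 2)
  expect_equal(exposure_duration(c(1, 1, 9), cutoff = 3), 0)
  # boundary: score equal to cutoff counts as high
  expect_equal(exposure_duration(c(3, 0, 0), cutoff = 3), 2)
  expect_equal(exposure_duration(c(0, 0, 5), window_waves = c(2, 3), cutoff = 3), 2)
  expect_error(exposure_duration(c(1, NA, 1), cutoff = 3), "missing")
  expect_error(exposure_duration(c(1, 1), window_waves = c(1, 5), cutoff = 3))
})

test_that("symptom slope is the OLS slope against years since first visit", {
  expect_equal(symptom_slope(c(1, 2, 3), c(0, 2, 4)), 0.5)
  expect_equal(symptom_slope(c(6, 4, 2), c(0, 2, 4)), -1)
  expect_equal(symptom_slope(c(4, 4, 4), c(0, 2, 4)), 0)
  set.seed(3)
  s <- runif(5); tt <- sort(runif(5))
  expect_equal(symptom_slope(s, tt), unname(coef(lm(s ~ tt))[2]))
})

test_that("pattern classification is exhaustive, exclusive, and maps ties to decrease", {
  expect_equal(time_course_pattern(c(5, 3, 1)), "decrease_decrease")
  expect_equal(time_course_pattern(c(1, 3, 2)), "increase_decrease")
  expect_equal(time_course_pattern(c(2, 2, 5)), "decrease_increase")
  # brute force over every integer triple on the 0-8 scale
  triples <- expand.grid(s1 = 0:8, s2 = 0:8, s3 = 0:8)
  pats <- apply(triples, 1, time_course_pattern)
  expect_true(all(pats %in% c("decrease_decrease", "decrease_increase",
                              "increase_decrease", "increase_increase")))
  # independent reconstruction of the rule
  expected <- paste(ifelse(triples$s2 - triples$s1 > 0, "increase", "decrease"),
                    ifelse(triples$s3 - triples$s2 > 0, "increase", "decrease"),
                    sep = "_")
  expect_identical(unname(pats), expected)
})

test_that("raising any score never decreases cumds, cumads, or duration", {
  set.seed(19)
  for (rep in 1:25) {
    s <- sample(0:8, 3, replace = TRUE)
    tt <- c(0, 2, 4)
    i <- sample(3, 1)
    s2 <- s; s2[i] <- s2[i] + sample(1:3, 1)
    expect_gte(cumulative_score(s2, tt), cumulative_score(s, tt))
    expect_gte(cumulative_average(s2, tt), cumulative_average(s, tt))
    expect_gte(exposure_duration(s2, cutoff = 3), exposure_duration(s, cutoff = 3))
  }
})

test_that("quartile assignment partitions symmetrically with quartile medians", {
  q <- assign_quartiles(1:8)
  expect_equal(q$labels, rep(1:4, each = 2))
  expect_equal(q$medians, c(1.5, 3.5, 5.5, 7.5))
  expect_error(assign_quartiles(rep(2, 10)), "degenerate")
  expect_error(assign_quartiles(1:5), "at least 8")
  # near-equal occupancy on a continuous sample, counted by brute force
  set.seed(5)
  v <- runif(1000)
  q2 <- assign_quartiles(v)
  expect_true(all(abs(tabulate(q2$labels, 4) - 250) <= 1))
  # ties at a breakpoint go to the lower quartile: for 1..9 the
  # interpolated 25th percentile is exactly 3
  v3 <- 1:9
  q3 <- assign_quartiles(v3)
  expect_equal(q3$breakpoints[1], 3)
  expect_equal(q3$labels[v3 == 3], 1L)
})

test_that("derive_exposures agrees with the scalar primitives row by row", {
  co <- quick_cohort(n = 120, seed = 9)
  ex <- derive_exposures(co, cutoff = 3)
  panel <- co$panel
  for (i in sample(nrow(ex), 10)) {
    rows <- panel[panel$id == ex$id[i], ]
    expect_equal(ex$cumds[i], cumulative_score(rows$score, rows$time))
    expect_equal(ex$cumads[i], cumulative_average(rows$score, rows$time))
    expect_equal(ex$burden_value[i],
                 cumulative_burden(rows$score, rows$time, 3)$burden_value)
    expect_equal(ex$duration_years[i],
                 exposure_duration(rows$score, cutoff = 3))
    expect_equal(ex$slope[i], symptom_slope(rows$score, rows$time))
    expect_equal(as.character(ex$pattern[i]), time_course_pattern(rows$score))
  }
  # participants with a missing score are excluded, not imputed
  panel$score[panel$id == 1] <- NA
  ex2 <- derive_exposures(panel, cutoff = 3)
  expect_false(1 %in% ex2$id)
  expect_equal(attr(ex2, "n_excluded"), 1L)
})
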