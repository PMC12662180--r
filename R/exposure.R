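#' Cumulative depressive-symptom score (trapezoid rule)
#'
#' Integrates the piecewise-linear symptom trajectory over the exposure
#' window: the average of each successive pair of visit scores is multiplied
#' by the interval in years between those visits and the products are summed.
#' The result is in score-years.
#'
#' @param scores Numeric vector of visit scores, one per wave, no missing.
#' @param times Numeric vector of visit times in years, strictly increasing.
#' @return Cumulative score in score-years.
#' @examples
#' cumulative_score(c(2, 4, 6), c(0, 2, 4))  # 16
#' @seealso [cumulative_average()], [cumulative_burden()]
#' @export
cumulative_score <- function(scores, times) {
  check_series(scores, times, min_waves = 2L)
  w <- length(scores)
  sum((scores[-w] + scores[-1]) / 2 * diff(times))
}

#' Cumulative average depressive-symptom score
#'
#' The cumulative score divided by the length of the exposure window: a
#' time-weighted mean score, bounded by the minimum and maximum observed
#' score and invariant to the time unit.
#'
#' @inheritParams cumulative_score
#' @return Time-weighted mean score (score units).
#' @examples
#' cumulative_average(c(2, 4, 6), c(0, 2, 4))  # 4
#' @export
cumulative_average <- function(scores, times) {
  check_series(scores, times, min_waves = 2L)
  span <- times[length(times)] - times[1]
  if (span <= 0) stop("zero-length exposure window")
  cumulative_score(scores, times) / span
}

#' Cumulative symptom burden relative to a cutoff
#'
#' The cumulative score centered on a cutoff: the trapezoid integral of
#' (score - cutoff), equal to `cumds - cutoff * (t_W - t_1)`. The sign
#' dichotomizes sustained exposure: participants with any non-negative
#' burden are classified `"nonnegative"` (boundary inclusive), the rest
#' `"negative"`.
#'
#' @inheritParams cumulative_score
#' @param cutoff Score-unit centering constant (typically the
#'   outcome-oriented cutoff of [optimal_cutoff()] or a screening threshold).
#' @return List with `burden_value` (signed score-years) and `burden_class`
#'   (`"negative"` or `"nonnegative"`).
#' @examples
#' cumulative_burden(c(2, 4, 6), c(0, 2, 4), cutoff = 3)
#' @export
cumulative_burden <- function(scores, times, cutoff) {
  check_series(scores, times, min_waves = 2L)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  span <- times[length(times)] - times[1]
  value <- cumulative_score(scores, times) - cutoff * span
  list(burden_value = value,
       burden_class = if (value >= 0) "nonnegative" else "negative")
}

#' High-symptom exposure duration over a two-visit window
#'
#' Counts the visits within a designated two-wave window whose score meets or
#' exceeds the cutoff, and converts the count to years at the biennial visit
#' cadence: 0, 2 or 4 years of high-symptom exposure.
#'
#' @param scores Full vector of wave scores.
#' @param window_waves Integer pair of wave indices defining the window
#'   (default waves 1 and 2).
#' @param cutoff High-symptom score cutoff; a visit counts when
#'   `score >= cutoff`.
#' @param years_per_wave Years credited per high visit (default 2, the
#'   biennial spacing).
#' @return Duration in years: 0, 2 or 4 at defaults.
#' @examples
#' exposure_duration(c(5, 5, 1), cutoff = 3)  # 4
#' @export
exposure_duration <- function(scores, window_waves = c(1L, 2L), cutoff,
                              years_per_wave = 2) {
  stopifnot(length(window_waves) == 2L)
  if (any(window_waves < 1L) || any(window_waves > length(scores)))
    stop("window waves outside the observed waves")
  s <- scores[window_waves]
  if (anyNA(s)) stop("missing score in the duration window")
  years_per_wave * sum(s >= cutoff)
}

#' Slope of the symptom trajectory
#'
#' Ordinary least-squares slope of visit scores against years since the
#' first visit. The sign (< 0 vs >= 0) strata are used as a binary
#' progression exposure.
#'
#' @inheritParams cumulative_score
#' @return Slope in score units per year.
#' @examples
#' symptom_slope(c(1, 2, 3), c(0, 2, 4))  # 0.5
#' @export
symptom_slope <- function(scores, times) {
  check_series(scores, times, min_waves = 2L)
  tc <- times - mean(times)
  den <- sum(tc^2)
  if (den == 0) stop("all visit times identical")
  sum(tc * (scores - mean(scores))) / den
}

#' Time-course pattern of three-wave symptom change
#'
#' Classifies the two successive wave-to-wave changes into a four-way
#' pattern: decrease-decrease, decrease-increase, increase-decrease or
#' increase-increase. A zero change counts as "decrease" (the non-increase
#' side): the four-category scheme has no stable class, and the rule is
#' applied symmetrically to both transitions.
#'
#' @param scores Numeric vector of exactly 3 non-missing wave scores.
#' @return One of `"decrease_decrease"`, `"decrease_increase"`,
#'   `"increase_decrease"`, `"increase_increase"`.
#' @examples
#' time_course_pattern(c(5, 3, 1))
#' time_course_pattern(c(2, 2, 5))  # zero change -> "decrease" first leg
#' @export
time_course_pattern <- function(scores) {
  if (length(scores) != 3L || anyNA(scores))
    stop("exactly 3 non-missing scores required")
  leg <- function(d) if (d > 0) "increase" else "decrease"
  paste(leg(scores[2] - scores[1]), leg(scores[3] - scores[2]), sep = "_")
}

pattern_levels <- c("decrease_decrease", "decrease_increase",
                    "increase_decrease", "increase_increase")

#' Quartile assignment of a cohort exposure variable
#'
#' Breakpoints at the 25th/50th/75th percentiles (linear-interpolation
#' quantile rule, R type 7). Values equal to a breakpoint are assigned to the
#' lower quartile. Per-quartile medians of the variable are recorded for the
#' quartile-median trend test.
#'
#' @param values Numeric vector, n >= 8, finite.
#' @return Object of class `quartile_assignment`: list with `breakpoints`
#'   (3 values), `labels` (integer 1--4 per participant), and `medians`
#'   (per-quartile median of `values`).
#' @examples
#' assign_quartiles(1:8)
#' @export
assign_quartiles <- function(values) {
  if (length(values) < 8L) stop("need at least 8 values for quartiles")
  if (!all(is.finite(values))) stop("non-finite values")
  if (length(unique(values)) == 1L)
    stop("degenerate exposure: all values identical, single stratum")
  brk <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  labels <- as.integer(cut(values, breaks = c(-Inf, brk, Inf), right = TRUE,
                           labels = FALSE))
  medians <- vapply(1:4, function(q) {
    v <- values[labels == q]
    if (!length(v)) NA_real_ else stats::median(v)
  }, numeric(1))
  out <- list(breakpoints = brk, labels = labels, medians = medians)
  class(out) <- "quartile_assignment"
  out
}

#' @export
print.quartile_assignment <- function(x, ...) {
  cat("<quartile_assignment>\n")
  cat("  breakpoints:", format(x$breakpoints, digits = 4), "\n")
  cat("  medians:    ", format(x$medians, digits = 4), "\n")
  cat("  sizes:      ", tabulate(x$labels, 4), "\n")
  invisible(x)
}

#' Derive all exposure metrics for a cohort
#'
#' Computes, per participant, the full exposure profile from the wave-level
#' panel: cumulative score, cumulative average, cumulative burden (value and
#' class), high-symptom exposure duration, OLS slope and time-course pattern.
#' Participants with a missing score at any wave are dropped (no imputation);
#' the number excluded is attached as the `n_excluded` attribute.
#'
#' @param panel Long data frame with columns `id`, `time` (years since
#'   baseline) and `score`, or a cohort object from [simulate_cohort()].
#' @param cutoff Score cutoff used for both burden centering and the duration
#'   window.
#' @param duration_window Integer pair of wave indices for the duration
#'   metric (default waves 1--2).
#' @return Data frame with one row per participant: `id`, `cumds`, `cumads`,
#'   `burden_value`, `burden_class`, `duration_years`, `slope`, `pattern`.
#'   Attributes `cutoff` and `duration_window` record the configuration.
#' @export
derive_exposures <- function(panel, cutoff, duration_window = c(1L, 2L)) {
  if (inherits(panel, "dep_cohort")) panel <- panel$panel
  need <- c("id", "time", "score")
  if (!all(need %in% names(panel)))
    stop("panel must have columns id, time, score")
  panel <- panel[order(panel$id, panel$time), , drop = FALSE]
  complete <- tapply(panel$score, panel$id, function(s) !anyNA(s))
  keep_ids <- names(complete)[complete]
  n_excl <- sum(!complete)
  panel <- panel[panel$id %in% keep_ids, , drop = FALSE]

  ids <- unique(panel$id)
  wcount <- table(panel$id)
  if (length(unique(wcount)) != 1L)
    stop("all participants must share the same number of waves")
  w <- unname(wcount[1])
  if (w < 3L) stop("at least 3 waves required")

  S <- matrix(panel$score, ncol = w, byrow = TRUE)
  Tm <- matrix(panel$time, ncol = w, byrow = TRUE)
  ord_ids <- panel$id[seq(1, nrow(panel), by = w)]

  dt <- Tm[, -1, drop = FALSE] - Tm[, -w, drop = FALSE]
  if (any(dt <= 0)) stop("visit times must be strictly increasing")
  mid <- (S[, -1, drop = FALSE] + S[, -w, drop = FALSE]) / 2
  cumds <- rowSums(mid * dt)
  span <- Tm[, w] - Tm[, 1]
  cumads <- cumds / span
  burden <- cumds - cutoff * span

  dw <- as.integer(duration_window)
  if (any(dw < 1L) || any(dw > w)) stop("duration window outside waves")
  dur <- 2 * ((S[, dw[1]] >= cutoff) + (S[, dw[2]] >= cutoff))

  tbar <- rowMeans(Tm); sbar <- rowMeans(S)
  tc <- Tm - tbar
  slope <- rowSums(tc * (S - sbar)) / rowSums(tc^2)

  d1 <- S[, 2] - S[, 1]; d2 <- S[, 3] - S[, 2]
  pattern <- paste(ifelse(d1 > 0, "increase", "decrease"),
                   ifelse(d2 > 0, "increase", "decrease"), sep = "_")

  out <- data.frame(
    id = ord_ids,
    cumds = cumds,
    cumads = cumads,
    burden_value = burden,
    burden_class = factor(ifelse(burden >= 0, "nonnegative", "negative"),
                          levels = c("negative", "nonnegative")),
    duration_years = dur,
    slope = slope,
    slope_class = factor(ifelse(slope >= 0, "nonneg", "neg"),
                         levels = c("neg", "nonneg")),
    pattern = factor(pattern, levels = pattern_levels),
    stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "duration_window") <- dw
  attr(out, "n_excluded") <- n_excl
  out
}

check_series <- function(scores, times, min_waves = 2L) {
  if (length(scores) != length(times))
    stop("scores and times must have equal length")
  if (length(scores) < min_waves)
    stop(sprintf("at least %d waves required", min_waves))
  if (anyNA(scores) || anyNA(times)) stop("missing score or time")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  invisible(TRUE)
}
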