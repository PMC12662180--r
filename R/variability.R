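#' Per-person visit-to-visit summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (SD / mean) of a participant's visit scores. The CV is undefined
#' (NA) when the mean is not positive.
#'
#' @param scores Numeric vector of >= 2 non-missing visit scores.
#' @return List with `mean`, `sd`, `cv`.
#' @examples
#' per_person_stats(c(0, 4))  # mean 2, sd 2.83, cv 1.41
#' @export
per_person_stats <- function(scores) {
  if (length(scores) < 2L || anyNA(scores))
    stop("need >= 2 non-missing scores")
  m <- mean(scores)
  s <- stats::sd(scores)
  list(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_)
}

#' Cohort-level calibration of variation independent of the mean
#'
#' Fits the log-log regression ln(SD) on ln(mean) across participants; the
#' slope is the exponent beta used by [vim_value()]. Participants with zero
#' SD or non-positive mean cannot enter the log-log fit and are excluded
#' (their count is recorded).
#'
#' @param means Per-person mean scores.
#' @param sds Per-person visit-to-visit SDs.
#' @return Object of class `vim_calibration`: list with `beta`, `intercept`,
#'   `n_used`, `n_excluded`.
#' @export
fit_vim_beta <- function(means, sds) {
  stopifnot(length(means) == length(sds))
  ok <- is.finite(means) & is.finite(sds) & means > 0 & sds > 0
  n_used <- sum(ok)
  if (n_used < 3L) stop("fewer than 3 participants eligible for calibration")
  lx <- log(means[ok]); ly <- log(sds[ok])
  if (stats::var(lx) == 0) stop("zero variance in ln(mean)")
  fit <- stats::lm.fit(cbind(1, lx), ly)
  out <- list(beta = unname(fit$coefficients[2]),
              intercept = unname(fit$coefficients[1]),
              n_used = n_used,
              n_excluded = length(means) - n_used)
  class(out) <- "vim_calibration"
  out
}

#' @export
print.vim_calibration <- function(x, ...) {
  cat(sprintf("<vim_calibration> beta = %.4f (intercept %.4f), n used = %d, excluded = %d\n",
              x$beta, x$intercept, x$n_used, x$n_excluded))
  invisible(x)
}

#' Variation independent of the mean
#'
#' VIM = 100 * SD / mean^beta, with beta from the cohort-level log-log
#' calibration of [fit_vim_beta()]. Reduces to 100 * CV when beta = 1 and to
#' 100 * SD when beta = 0. Undefined for non-positive means.
#'
#' @param sd Per-person SD.
#' @param mean Per-person mean (must be > 0).
#' @param calibration A `vim_calibration` object (or a bare numeric beta).
#' @return VIM value(s); NA where mean <= 0.
#' @export
vim_value <- function(sd, mean, calibration) {
  beta <- if (inherits(calibration, "vim_calibration")) calibration$beta
          else as.numeric(calibration)
  ifelse(is.finite(mean) & mean > 0, 100 * sd / mean^beta, NA_real_)
}

#' Add visit-to-visit variability columns to a cohort
#'
#' Computes per-person mean/SD/CV from the wave-level panel, fits the VIM
#' calibration over eligible participants, and returns a participant-level
#' data frame with `score_mean`, `score_sd`, `cv`, `vim`. Participants
#' excluded from calibration (zero SD or non-positive mean) still receive SD
#' (and CV where defined) but no VIM.
#'
#' @param panel Long panel data frame (`id`, `time`, `score`) or a cohort
#'   object from [simulate_cohort()].
#' @return Data frame with one row per participant and a `calibration`
#'   attribute holding the `vim_calibration`.
#' @export
add_variability <- function(panel) {
  if (inherits(panel, "dep_cohort")) panel <- panel$panel
  panel <- panel[order(panel$id, panel$time), , drop = FALSE]
  sp <- split(panel$score, panel$id)
  sp <- sp[vapply(sp, function(s) length(s) >= 2L && !anyNA(s), logical(1))]
  ids <- names(sp)
  m <- vapply(sp, mean, numeric(1))
  s <- vapply(sp, stats::sd, numeric(1))
  cv <- ifelse(m > 0, s / m, NA_real_)
  cal <- fit_vim_beta(m, s)
  vim <- ifelse(m > 0 & s > 0, vim_value(s, m, cal), NA_real_)
  out <- data.frame(id = ids, score_mean = unname(m), score_sd = unname(s),
                    cv = unname(cv), vim = unname(vim),
                    stringsAsFactors = FALSE)
  # panel ids may be numeric; restore the original type for joins
  if (is.numeric(panel$id)) out$id <- as.numeric(out$id)
  attr(out, "calibration") <- cal
  out
}
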