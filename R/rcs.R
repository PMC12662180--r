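#' Restricted cubic spline basis (truncated-power form)
#'
#' Natural cubic spline basis constrained to linearity beyond the boundary
#' knots, in the truncated-power parameterization: the first column is the
#' raw variable (the linear term) and the remaining k - 2 columns are the
#' nonlinear terms, normalized by the squared span of the knots. This
#' separable linear/nonlinear structure is what the nonlinearity Wald test
#' relies on.
#'
#' @param x Numeric vector.
#' @param knots Numeric vector of k >= 3 distinct interior knot locations.
#' @return Matrix with k - 1 columns and attribute `knots`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3L) stop("need at least 3 knots")
  tau <- (knots[k] - knots[1])^2
  pp <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1L)
  out[, 1] <- x
  for (j in seq_len(k - 2L)) {
    out[, j + 1L] <- (pp(x - knots[j]) -
      pp(x - knots[k - 1L]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1L]) +
      pp(x - knots[k]) * (knots[k - 1L] - knots[j]) / (knots[k] - knots[k - 1L])) / tau
  }
  colnames(out) <- paste0("rcs", seq_len(k - 1L))
  attr(out, "knots") <- knots
  out
}

#' Quantile knot placements for restricted cubic splines
#'
#' The standard percentile recipes: 3 knots at 10/50/90%, 4 knots at
#' 5/35/65/95%, 5 knots at 5/27.5/50/72.5/95%.
#'
#' @param x Numeric vector.
#' @param nk Number of knots (3, 4 or 5).
#' @return Numeric vector of knot locations.
#' @export
rcs_knots <- function(x, nk) {
  probs <- switch(as.character(nk),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop("supported knot counts: 3, 4, 5"))
  unname(stats::quantile(x, probs, type = 7))
}

#' BIC-selected restricted cubic spline Cox fit
#'
#' Fits the exposure through a restricted cubic spline inside the adjusted
#' Cox model for each candidate knot count, selects the knot count
#' minimizing BIC (-2 partial log-likelihood + p * ln(events)), and reports
#' the Wald test of all spline terms (`p_overall`), the Wald test of the
#' nonlinear terms only (`p_nonlinear`), and the fitted log hazard-ratio
#' curve with pointwise 95% CI relative to a reference exposure value
#' (default: the cohort median).
#'
#' @param data Participant-level data frame.
#' @param exposure Continuous exposure column name.
#' @param model Model ladder id, see [model_covariates()].
#' @param candidate_knots Integer vector of knot counts to compare
#'   (default 3:5).
#' @param ref Reference exposure value anchoring the curve (default
#'   median).
#' @param grid_length Number of grid points for the reported curve.
#' @return Object of class `dep_splinefit`: list with `knots`, `chosen_k`,
#'   `bic` (per candidate), `p_overall`, `p_nonlinear`, `curve` (data frame:
#'   exposure, loghr, se, lo, hi), `ref`, `fit`.
#' @export
rcs_fit <- function(data, exposure, model = "M4", candidate_knots = 3:5,
                    ref = NULL, grid_length = 100L) {
  covs <- model_covariates(model)
  used <- unique(c("time_years", "event", exposure, covs))
  dat <- data[stats::complete.cases(data[used]), , drop = FALSE]
  x <- dat[[exposure]]
  if (length(unique(x)) < max(candidate_knots))
    stop("insufficient distinct exposure values for the candidate knots")
  events <- sum(dat$event)
  if (events < 1) stop("zero events")

  fits <- list(); bics <- numeric(0)
  for (nk in candidate_knots) {
    kn <- rcs_knots(x, nk)
    if (length(unique(kn)) < nk) { bics[as.character(nk)] <- Inf; next }
    B <- rcs_basis(x, kn)
    dd <- cbind(dat, as.data.frame(B))
    fml <- cox_formula(colnames(B), covs)
    fit <- survival::coxph(fml, data = dd, ties = "efron")
    if (any(is.na(stats::coef(fit)))) { bics[as.character(nk)] <- Inf; next }
    p <- length(stats::coef(fit))
    bics[as.character(nk)] <- -2 * fit$loglik[length(fit$loglik)] +
      p * log(events)
    fits[[as.character(nk)]] <- list(fit = fit, knots = kn, basis_cols = colnames(B))
  }
  if (!length(fits)) stop("no valid spline fit (collinear basis?)")
  chosen <- names(which.min(bics))
  best <- fits[[chosen]]
  spline_terms <- best$basis_cols
  nonlinear_terms <- spline_terms[-1]
  p_overall <- wald_block(best$fit, spline_terms)$p
  p_nonlinear <- wald_block(best$fit, nonlinear_terms)$p

  if (is.null(ref)) ref <- stats::median(x)
  grid <- seq(min(x), max(x), length.out = grid_length)
  Bg <- rcs_basis(grid, best$knots)
  Br <- rcs_basis(ref, best$knots)
  Dm <- sweep(Bg, 2, Br[1, ])
  beta <- stats::coef(best$fit)[spline_terms]
  V <- stats::vcov(best$fit)[spline_terms, spline_terms, drop = FALSE]
  loghr <- drop(Dm %*% beta)
  se <- sqrt(rowSums((Dm %*% V) * Dm))
  curve <- data.frame(exposure = grid, loghr = loghr, se = se,
                      lo = loghr - 1.96 * se, hi = loghr + 1.96 * se)

  out <- list(knots = best$knots, chosen_k = as.integer(chosen),
              bic = bics, p_overall = p_overall, p_nonlinear = p_nonlinear,
              curve = curve, ref = ref, events = events, fit = best$fit)
  class(out) <- "dep_splinefit"
  out
}

#' @export
print.dep_splinefit <- function(x, ...) {
  cat(sprintf("<dep_splinefit> %d knots chosen by BIC (candidates: %s)\n",
              x$chosen_k, paste(names(x$bic), collapse = ", ")))
  cat(sprintf("  p_overall = %.4g, p_nonlinear = %.4g, reference = %.3g\n",
              x$p_overall, x$p_nonlinear, x$ref))
  invisible(x)
}

#' Kaplan-Meier estimates by group with log-rank comparison
#'
#' Product-limit survival per group via [survival::survfit()], compared
#' across groups with the package's k-group log-rank test.
#'
#' @param data Participant-level data with `time_years` and `event`.
#' @param group Grouping vector (e.g. quartile labels), aligned with
#'   `data`.
#' @return Object of class `dep_km`: list with `table` (group, time, surv,
#'   n_risk, n_event), `logrank` (chisq, df, p), `fit`.
#' @export
km_estimate <- function(data, group) {
  g <- factor(group)
  if (any(tabulate(g, nlevels(g)) == 0L)) stop("empty group")
  dat <- data.frame(time_years = data$time_years, event = data$event, g = g)
  fit <- survival::survfit(survival::Surv(time_years, event) ~ g, data = dat)
  strata_names <- if (is.null(fit$strata)) levels(g) else
    sub("^g=", "", names(fit$strata))
  grp <- if (is.null(fit$strata)) rep(strata_names, length(fit$time)) else
    rep(strata_names, fit$strata)
  tab <- data.frame(group = grp, time = fit$time, surv = fit$surv,
                    n_risk = fit$n.risk, n_event = fit$n.event,
                    stringsAsFactors = FALSE)
  lr <- if (nlevels(g) >= 2 && sum(dat$event) >= 1)
    logrank_test(dat$time_years, dat$event, dat$g) else NULL
  out <- list(table = tab, logrank = lr, fit = fit)
  class(out) <- "dep_km"
  out
}

#' @export
print.dep_km <- function(x, ...) {
  ng <- length(unique(x$table$group))
  cat(sprintf("<dep_km> %d groups", ng))
  if (!is.null(x$logrank))
    cat(sprintf("; log-rank chi-square %.3f (df %d), p = %.3g",
                x$logrank$chisq, x$logrank$df, x$logrank$p))
  cat("\n")
  invisible(x)
}
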