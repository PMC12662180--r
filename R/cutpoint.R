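#' k-group log-rank test
#'
#' Standard log-rank chi-square statistic: over the ordered distinct event
#' times, observed minus expected events per group are accumulated given the
#' risk-set composition, with the hypergeometric (co)variance; the statistic
#' is the quadratic form over the first k - 1 groups. For two groups this is
#' the familiar (sum(O - E))^2 / sum(V).
#'
#' @param time Follow-up times.
#' @param event Event indicator (0/1).
#' @param group Group labels (2 or more non-empty groups).
#' @return List with `chisq`, `df`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("need at least two groups")
  if (any(tabulate(group, k) == 0L)) stop("empty group")
  if (sum(event) < 1L) stop("no events")

  ut <- sort(unique(time[event == 1]))
  # risk sets and event counts per group at each distinct event time
  G <- stats::model.matrix(~ group - 1)                # n x k
  atrisk <- outer(ut, time, "<=")                      # J x n
  R <- atrisk %*% G                                    # J x k at-risk
  isev <- t(vapply(ut, function(u) event == 1 & time == u,
                   logical(length(time))))             # J x n
  D <- isev %*% G                                      # J x k events
  nj <- rowSums(R); dj <- rowSums(D)

  E <- R * (dj / nj)
  OE <- colSums(D) - colSums(E)

  # hypergeometric covariance, guarding risk sets of size 1
  fac <- ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0)
  V <- matrix(0, k, k)
  P <- R / nj
  for (i in seq_len(k)) {
    for (l in seq_len(k)) {
      V[i, l] <- if (i == l) sum(fac * P[, i] * (1 - P[, i]))
                 else       -sum(fac * P[, i] * P[, l])
    }
  }
  idx <- seq_len(k - 1L)
  Vi <- V[idx, idx, drop = FALSE]
  chisq <- tryCatch(
    drop(t(OE[idx]) %*% solve(Vi, OE[idx])),
    error = function(e) {
      # singular variance (e.g. a group exhausted early): generalized inverse
      sv <- svd(Vi)
      pos <- sv$d > max(sv$d) * 1e-10
      ginv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      drop(t(OE[idx]) %*% ginv %*% OE[idx])
    })
  list(chisq = chisq, df = k - 1L,
       p = stats::pchisq(chisq, k - 1L, lower.tail = FALSE),
       observed = colSums(D), expected = colSums(E))
}

#' Two-sample log-rank chi-square statistic
#'
#' Convenience wrapper around [logrank_test()] for a binary split; returns
#' the scalar chi-square on 1 degree of freedom.
#'
#' @inheritParams logrank_test
#' @return Chi-square statistic (numeric scalar).
#' @export
logrank_statistic <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("logrank_statistic expects exactly two groups")
  logrank_test(time, event, g)$chisq
}

#' Candidate cutoffs for outcome-oriented dichotomization
#'
#' All distinct observed score values c such that the split "score >= c"
#' leaves both groups with at least `min_group_fraction` of the sample.
#'
#' @param scores Observed scores to search over.
#' @param min_group_fraction Minimum fraction of the sample in each group
#'   (0 < f < 0.5; default 0.10, the usual guard against degenerate extreme
#'   splits in maximally selected statistics).
#' @return Numeric vector of candidate cutoffs (sorted increasing).
#' @export
candidate_cutoffs <- function(scores, min_group_fraction = 0.10) {
  stopifnot(all(is.finite(scores)))
  if (min_group_fraction <= 0 || min_group_fraction >= 0.5)
    stop("min_group_fraction must be in (0, 0.5)")
  n <- length(scores)
  vals <- sort(unique(scores))
  nmin <- min_group_fraction * n
  ok <- vapply(vals, function(c) {
    nh <- sum(scores >= c)
    nh >= nmin && (n - nh) >= nmin
  }, logical(1))
  cand <- vals[ok]
  if (!length(cand))
    stop("no candidate cutoff satisfies the group-size constraint")
  cand
}

#' Outcome-oriented optimal cutoff by maximally selected log-rank statistics
#'
#' Evaluates the two-sample log-rank statistic at every candidate cutoff
#' ("score >= c" defines the high group; ties at the cutoff go high) and
#' returns the maximizer. Ties in the statistic break to the smallest
#' cutoff. The full candidate grid is retained for audit. No selection
#' p-value is computed: the cutoff is used only to define exposure strata.
#'
#' @param scores Score per participant (the dichotomization variable).
#' @param time Follow-up times.
#' @param event Event indicator (0/1).
#' @param min_group_fraction Passed to [candidate_cutoffs()].
#' @return Object of class `cutpoint_result`: list with `cutoff`,
#'   `chi_square`, `grid` (data frame: cutoff, statistic, n_low, n_high) and
#'   `min_group_fraction`.
#' @export
optimal_cutoff <- function(scores, time, event, min_group_fraction = 0.10) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  cand <- candidate_cutoffs(scores, min_group_fraction)
  stat <- numeric(length(cand))
  n_high <- integer(length(cand))
  for (i in seq_along(cand)) {
    hi <- scores >= cand[i]
    n_high[i] <- sum(hi)
    stat[i] <- logrank_statistic(time, event, hi)
  }
  best <- which.max(stat)  # which.max returns the first (smallest cutoff) tie
  out <- list(cutoff = cand[best], chi_square = stat[best],
              grid = data.frame(cutoff = cand, statistic = stat,
                                n_low = length(scores) - n_high,
                                n_high = n_high),
              min_group_fraction = min_group_fraction)
  class(out) <- "cutpoint_result"
  out
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result> cutoff >= %g (log-rank chi-square %.3f over %d candidates)\n",
              x$cutoff, x$chi_square, nrow(x$grid)))
  invisible(x)
}
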