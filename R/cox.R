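#' Covariate sets of the nested model ladder
#'
#' Model 1 is unadjusted. Model 2 adds age, gender, marital status,
#' education level and residence; Model 3 adds smoking status, drinking
#' status, CRP, HbA1c, TC and HDL-C; Model 4 adds hypertension, diabetes,
#' heart disease and stroke. The sets are strictly nested.
#'
#' @param model One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return Character vector of covariate column names (empty for M1).
#' @export
model_covariates <- function(model = c("M4", "M1", "M2", "M3")) {
  model <- match.arg(model)
  m2 <- c("age", "gender", "marital", "education", "residence")
  m3 <- c(m2, "smoking", "drinking", "crp", "hba1c", "tc", "hdlc")
  m4 <- c(m3, "hypertension", "diabetes", "heart_disease", "stroke")
  switch(model, M1 = character(0), M2 = m2, M3 = m3, M4 = m4)
}

cox_formula <- function(exposure_terms, covariates) {
  rhs <- paste(c(exposure_terms, covariates), collapse = " + ")
  stats::as.formula(paste("survival::Surv(time_years, event) ~", rhs))
}

#' Cox proportional-hazards fit on an exposure coding
#'
#' Fits a Cox model (Efron ties by default) of follow-up time from baseline
#' on the given exposure term plus the model ladder's covariates, and
#' returns coefficient-level inference: hazard ratios with Wald 95%
#' confidence intervals on the log scale (`exp(coef +/- 1.96 se)`). For
#' factor exposures the lowest level is the reference. Non-convergence is
#' flagged, never silently returned.
#'
#' @param data Participant-level data frame with `time_years`, `event`, the
#'   exposure column(s) and the model covariates.
#' @param exposure Name of the exposure column (character), or a character
#'   vector of several terms fit jointly.
#' @param model Model ladder id, see [model_covariates()].
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param time_origin `"baseline"` (default) counts follow-up from the first
#'   wave; `"exposure_end"` is a landmark analysis counting from the end of
#'   the exposure window: participants whose follow-up ends at or before
#'   `landmark_years` are dropped and the clock restarts there, avoiding
#'   immortal time when exposure spans the waves.
#' @param landmark_years Landmark time for `time_origin = "exposure_end"`
#'   (default 4, the span of three biennial waves).
#' @return Object of class `dep_coxfit`: list with `table` (term, coef, se,
#'   hr, lo, hi, p), `exposure`, `model`, `n`, `events`, `loglik`,
#'   `converged`, and the underlying `fit`.
#' @export
fit_cox <- function(data, exposure, model = "M4", ties = "efron",
                    time_origin = c("baseline", "exposure_end"),
                    landmark_years = 4) {
  time_origin <- match.arg(time_origin)
  if (time_origin == "exposure_end") {
    data <- data[data$time_years > landmark_years, , drop = FALSE]
    if (!nrow(data)) stop("no participants at risk past the landmark")
    data$time_years <- data$time_years - landmark_years
  }
  covs <- model_covariates(model)
  used <- unique(c("time_years", "event", exposure, covs))
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  if (sum(dat$event) < 1) stop("zero events")
  for (v in c(exposure, covs)) {
    x <- dat[[v]]
    if ((is.factor(x) && nlevels(droplevels(x)) < 2L) ||
        (!is.factor(x) && length(unique(x)) < 2L))
      stop("constant covariate: ", v)
  }
  infinite_beta <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(cox_formula(exposure, covs), data = dat,
                    ties = ties, x = FALSE, model = FALSE),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("Ran out of iterations", msg))
        stop("Cox model did not converge")
      if (grepl("infinite", msg)) {
        infinite_beta <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (infinite_beta)
    warning("possible complete separation: a coefficient may be infinite")
  if (any(is.na(stats::coef(fit))))
    stop("Cox model dropped terms (collinearity or separation)")
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(term = rownames(co),
                    coef = co[, "coef"],
                    se = co[, "se(coef)"],
                    hr = exp(co[, "coef"]),
                    lo = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    hi = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(table = tab, exposure = exposure, model = model,
              n = fit$n, events = fit$nevent,
              loglik = fit$loglik[length(fit$loglik)],
              score = fit$score,
              converged = !infinite_beta, ties = ties,
              time_origin = time_origin, fit = fit)
  class(out) <- "dep_coxfit"
  out
}

#' @export
print.dep_coxfit <- function(x, digits = 3, ...) {
  cat(sprintf("<dep_coxfit> %s | exposure: %s | n = %d, events = %d\n",
              x$model, paste(x$exposure, collapse = " + "), x$n, x$events))
  tab <- x$table
  tab$hr <- round(tab$hr, digits); tab$lo <- round(tab$lo, digits)
  tab$hi <- round(tab$hi, digits)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "hr", "lo", "hi", "p")], row.names = FALSE)
  invisible(x)
}

#' Quartile-median trend test
#'
#' Replaces each participant's quartile label with that quartile's median
#' exposure value, refits the Cox model with this single continuous term,
#' and returns its Wald p-value: the standard test of monotone dose-response
#' across quartiles.
#'
#' @param data Participant-level data (`time_years`, `event`, covariates).
#' @param quartiles A `quartile_assignment` from [assign_quartiles()],
#'   aligned row-for-row with `data`.
#' @param model Model ladder id.
#' @return List with `p` (Wald p of the trend term), `coef`, `se` and the
#'   underlying `dep_coxfit`.
#' @export
trend_test <- function(data, quartiles, model = "M4") {
  stopifnot(inherits(quartiles, "quartile_assignment"),
            length(quartiles$labels) == nrow(data))
  if (anyNA(quartiles$medians)) stop("degenerate quartiles")
  data$trend_score <- quartiles$medians[quartiles$labels]
  fit <- fit_cox(data, "trend_score", model = model)
  row <- fit$table[fit$table$term == "trend_score", ]
  list(p = row$p, coef = row$coef, se = row$se, fit = fit)
}

#' Within-group z-standardization
#'
#' Centers and scales to unit sample SD within each group (e.g. within each
#' cohort), the harmonization used when instruments and score ranges differ
#' across cohorts.
#'
#' @param values Numeric vector.
#' @param group Optional grouping vector (default: one group).
#' @return Numeric vector of z-scores.
#' @export
zstandardize <- function(values, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(values))
  out <- stats::ave(values, group, FUN = function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) stop("zero SD within a group")
    (x - mean(x)) / s
  })
  out
}

wald_block <- function(fit, terms) {
  b <- stats::coef(fit)[terms]
  V <- stats::vcov(fit)[terms, terms, drop = FALSE]
  w <- drop(t(b) %*% solve(V, b))
  list(chisq = w, df = length(terms),
       p = stats::pchisq(w, length(terms), lower.tail = FALSE))
}

#' Subgroup analyses with interaction test
#'
#' Fits the model within each level of a subgroup variable (the variable is
#' removed from the covariate list inside its own strata) and tests
#' effect-measure modification with a Wald test on the exposure-by-subgroup
#' product terms in the pooled model. Strata with no events are skipped and
#' reported.
#'
#' @param data Participant-level data frame.
#' @param exposure Exposure column name (continuous or binary).
#' @param subgroup Name of a factor (or coercible) column to stratify on.
#' @param model Model ladder id.
#' @return List with `strata` (named list of `dep_coxfit`), `interaction_p`,
#'   `skipped` (levels without events).
#' @export
subgroup_analysis <- function(data, exposure, subgroup, model = "M4") {
  g <- factor(data[[subgroup]])
  covs <- setdiff(model_covariates(model), subgroup)
  strata <- list(); skipped <- character(0)
  for (lev in levels(g)) {
    sub <- data[g == lev & !is.na(g), , drop = FALSE]
    if (!nrow(sub) || sum(sub$event, na.rm = TRUE) < 1) {
      skipped <- c(skipped, lev); next
    }
    strata[[lev]] <- fit_cox_with_covs(sub, exposure, covs)
  }
  # pooled model with product term
  dat <- data
  dat$.sub <- g
  pooled <- fit_cox_with_covs(dat, c(exposure, ".sub",
                                     paste0(exposure, ":.sub")), covs)
  inter_terms <- grep(":", pooled$table$term, value = TRUE, fixed = TRUE)
  wb <- wald_block(pooled$fit, inter_terms)
  list(strata = strata, interaction_p = wb$p, interaction_chisq = wb$chisq,
       pooled = pooled, skipped = skipped)
}

fit_cox_with_covs <- function(data, exposure_terms, covs) {
  plain <- exposure_terms[!grepl(":", exposure_terms)]
  used <- unique(c("time_years", "event", plain, covs))
  dat <- data[stats::complete.cases(data[used]), , drop = FALSE]
  if (sum(dat$event) < 1) stop("zero events")
  fit <- survival::coxph(cox_formula(exposure_terms, covs), data = dat,
                         ties = "efron")
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), coef = sm[, "coef"],
                    se = sm[, "se(coef)"], hr = exp(sm[, "coef"]),
                    lo = exp(sm[, "coef"] - 1.96 * sm[, "se(coef)"]),
                    hi = exp(sm[, "coef"] + 1.96 * sm[, "se(coef)"]),
                    p = sm[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- list(table = tab, exposure = exposure_terms, model = "custom",
              n = fit$n, events = fit$nevent,
              loglik = fit$loglik[length(fit$loglik)], converged = TRUE,
              ties = "efron", fit = fit)
  class(out) <- "dep_coxfit"
  out
}

#' Complete-case logistic sensitivity analysis
#'
#' Maximum-likelihood logistic regression of the ever-dementia indicator on
#' the exposure with the same covariate ladder, on complete cases only.
#' Reports odds ratios with Wald 95% CIs and the number of rows dropped.
#'
#' @param data Participant-level data with `event` as the binary outcome.
#' @param exposure Exposure column name.
#' @param model Model ladder id.
#' @return List with `table` (term, or, lo, hi, p), `n`, `cases`,
#'   `n_dropped`, `fit`.
#' @export
logistic_sensitivity <- function(data, exposure, model = "M4") {
  covs <- model_covariates(model)
  used <- unique(c("event", exposure, covs))
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[used])
  dat <- data[cc, used, drop = FALSE]
  if (sum(dat$event) < 1) stop("zero cases")
  rhs <- paste(c(exposure, covs), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste("event ~", rhs)),
                    family = stats::binomial(), data = dat)
  if (!fit$converged) stop("logistic model did not converge")
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  tab <- data.frame(term = rownames(sm), coef = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    or = exp(sm[, "Estimate"]),
                    lo = exp(sm[, "Estimate"] - 1.96 * sm[, "Std. Error"]),
                    hi = exp(sm[, "Estimate"] + 1.96 * sm[, "Std. Error"]),
                    p = sm[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  list(table = tab, n = nrow(dat), cases = sum(dat$event),
       n_dropped = sum(!cc), fit = fit)
}
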