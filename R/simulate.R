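#' Simulation configuration for a synthetic panel cohort
#'
#' Assembles the generating model for [simulate_cohort()]: bounded integer
#' symptom trajectories over biennial waves (person intercept + person slope
#' x time + visit noise, rounded half-away-from-zero and clipped to the scale
#' range), a covariate mix resembling aging-cohort marginals, and event times
#' from an exponential-baseline proportional-hazards model whose linear
#' predictor applies user-specified true log hazard ratios to each
#' participant's derived exposures and covariates.
#'
#' Trajectory defaults are scale-specific and chosen so the marginal
#' prevalence of screening-positive visits matches the 18--32% range typical
#' of these instruments in population panels (see the package vignette).
#'
#' @param n_participants Number of participants (> 0).
#' @param scale A [depression_scale()] or scale name.
#' @param n_waves Number of exposure waves (>= 3; default 3).
#' @param wave_spacing_years Spacing between waves (default 2).
#' @param trajectory Optional list overriding any of `intercept_mean`,
#'   `intercept_sd`, `slope_mean`, `slope_sd`, `noise_sd`.
#' @param betas Named list of true log hazard ratios keyed by exposure term:
#'   `cumds`, `cumads`, `cumads_z` (per within-cohort SD of cumads),
#'   `burden` (nonnegative vs negative), `duration2`/`duration4` (vs 0
#'   years), `slope_bin` (>= 0 vs < 0), `score_sd`, `cv`. Terms not named
#'   have true effect 0.
#' @param covariate_betas Named list of true log hazard ratios for covariate
#'   columns (default: all zero).
#' @param baseline_hazard Exponential baseline hazard per year (default
#'   0.012, giving roughly 12% cumulative incidence over the default
#'   follow-up under the null).
#' @param censor_time_years Administrative censoring time from baseline
#'   (default 10.8, the pooled median follow-up of the emulated designs);
#'   must exceed the exposure-window length.
#' @param duration_cutoff Cutoff used when duration-category effects are
#'   generated (default: the scale's screening threshold).
#' @param duration_window Wave indices of the duration window (default 1:2).
#' @param dropout_rate Per-participant probability of random early censoring
#'   (uniform over follow-up); default 0.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants,
                       scale = "CESD8",
                       n_waves = 3L,
                       wave_spacing_years = 2,
                       trajectory = list(),
                       betas = list(),
                       covariate_betas = list(),
                       baseline_hazard = 0.012,
                       censor_time_years = 10.8,
                       duration_cutoff = NULL,
                       duration_window = c(1L, 2L),
                       dropout_rate = 0,
                       seed = 1L) {
  scale <- as_depression_scale(scale)
  if (n_participants <= 0) stop("n_participants must be positive")
  if (n_waves < 3L) stop("need at least 3 waves")
  if (wave_spacing_years <= 0) stop("wave spacing must be positive")
  if (baseline_hazard <= 0) stop("baseline hazard must be positive")
  window_len <- (n_waves - 1L) * wave_spacing_years
  if (censor_time_years <= window_len)
    stop("censoring time must exceed the exposure-window length")

  traj_default <- switch(scale$name,
    CESD8  = list(intercept_mean = 1.0, intercept_sd = 1.5,
                  slope_mean = 0.05, slope_sd = 0.25, noise_sd = 0.9),
    CESD10 = list(intercept_mean = 7.5, intercept_sd = 4.0,
                  slope_mean = 0.10, slope_sd = 0.60, noise_sd = 2.0),
    EUROD  = list(intercept_mean = 2.3, intercept_sd = 1.5,
                  slope_mean = 0.05, slope_sd = 0.25, noise_sd = 0.9))
  traj <- utils::modifyList(traj_default, trajectory)
  if (any(unlist(traj[c("intercept_sd", "slope_sd", "noise_sd")]) < 0))
    stop("trajectory SDs must be non-negative")

  known <- c("cumds", "cumads", "cumads_z", "burden", "duration2",
             "duration4", "slope_bin", "score_sd", "cv")
  if (length(betas) && !all(names(betas) %in% known))
    stop("unknown exposure beta: ",
         paste(setdiff(names(betas), known), collapse = ", "))

  out <- list(n_participants = as.integer(n_participants), scale = scale,
              n_waves = as.integer(n_waves),
              wave_spacing_years = wave_spacing_years, trajectory = traj,
              betas = betas, covariate_betas = covariate_betas,
              baseline_hazard = baseline_hazard,
              censor_time_years = censor_time_years,
              duration_cutoff = duration_cutoff %||% scale$high_threshold,
              duration_window = as.integer(duration_window),
              dropout_rate = dropout_rate, seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

simulate_covariates <- function(n) {
  edu_lev <- c("Below high school", "High school", "College or above")
  data.frame(
    age = pmin(pmax(round(stats::rnorm(n, 64, 8)), 45), 90),
    gender = factor(ifelse(stats::runif(n) < 0.55, "Female", "Male"),
                    levels = c("Male", "Female")),
    marital = factor(ifelse(stats::runif(n) < 0.70, "Married", "Others"),
                     levels = c("Others", "Married")),
    education = factor(sample(edu_lev, n, replace = TRUE,
                              prob = c(0.35, 0.35, 0.30)), levels = edu_lev),
    residence = factor(ifelse(stats::runif(n) < 0.75, "Urban", "Rural"),
                       levels = c("Rural", "Urban")),
    smoking = factor(sample(c("Never", "Former", "Current"), n, TRUE,
                            prob = c(0.50, 0.25, 0.25)),
                     levels = c("Never", "Former", "Current")),
    drinking = stats::rbinom(n, 1, 0.50),
    bmi = round(stats::rnorm(n, 26.5, 4), 1),
    sbp = round(stats::rnorm(n, 130, 15)),
    dbp = round(stats::rnorm(n, 78, 10)),
    crp = round(stats::rlnorm(n, 0.4, 0.8), 2),
    hba1c = round(stats::rnorm(n, 5.8, 0.7), 2),
    tc = round(stats::rnorm(n, 200, 35)),
    hdlc = round(stats::rnorm(n, 55, 14)),
    hypertension = stats::rbinom(n, 1, 0.44),
    diabetes = stats::rbinom(n, 1, 0.13),
    heart_disease = stats::rbinom(n, 1, 0.17),
    stroke = stats::rbinom(n, 1, 0.04),
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic panel cohort with known ground truth
#'
#' Generates `n_participants` with integer symptom trajectories over the
#' configured waves, a covariate block, and dementia event times from an
#' exponential-baseline proportional-hazards model. The linear predictor is
#' built from the participant's *derived* exposure metrics (computed with
#' the package's own exposure functions) and covariates, each multiplied by
#' its configured true log hazard ratio; exposure terms are mean-centered in
#' the linear predictor so that changing an effect size rescales relative
#' hazards without shifting the marginal incidence (centering is absorbed by
#' the baseline hazard and leaves fitted coefficients untouched).
#' Administrative censoring applies at `censor_time_years`.
#'
#' @param config A [sim_config()].
#' @return Object of class `dep_cohort`: list with `participants` (one row
#'   per participant: covariates, true linear predictor `lp_true`,
#'   `time_years`, `event`, `event_wave`), `panel` (one row per
#'   participant-wave: `id`, `wave`, `time`, `age`, `score`), `scale`,
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  w <- config$n_waves
  sc <- config$scale
  tr <- config$trajectory
  times <- (seq_len(w) - 1L) * config$wave_spacing_years

  cov <- simulate_covariates(n)

  a <- stats::rnorm(n, tr$intercept_mean, tr$intercept_sd)
  b <- stats::rnorm(n, tr$slope_mean, tr$slope_sd)
  latent <- outer(a, rep(1, w)) + outer(b, times) +
    matrix(stats::rnorm(n * w, 0, tr$noise_sd), n, w)
  S <- pmin(pmax(round_half_away(latent), sc$min_score), sc$max_score)

  # derived exposures on the generated trajectories (the generating model
  # treats cumulative exposure as a baseline-fixed covariate)
  dt <- diff(times)
  mid <- (S[, -1, drop = FALSE] + S[, -w, drop = FALSE]) / 2
  cumds <- as.vector(mid %*% dt)
  span <- times[w] - times[1]
  cumads <- cumds / span
  tc <- times - mean(times)
  slope <- as.vector((S - rowMeans(S)) %*% tc) / sum(tc^2)
  dw <- config$duration_window
  dur <- 2 * ((S[, dw[1]] >= config$duration_cutoff) +
              (S[, dw[2]] >= config$duration_cutoff))
  burden_nn <- as.numeric(cumds - config$duration_cutoff * span >= 0)
  score_sd <- apply(S, 1, stats::sd)
  score_mean <- rowMeans(S)
  cv <- ifelse(score_mean > 0, score_sd / score_mean, 0)
  sd_ads <- stats::sd(cumads)
  cumads_z <- if (sd_ads > 0) (cumads - mean(cumads)) / sd_ads else cumads * 0

  terms <- list(cumds = cumds, cumads = cumads, cumads_z = cumads_z,
                burden = burden_nn,
                duration2 = as.numeric(dur == 2),
                duration4 = as.numeric(dur == 4),
                slope_bin = as.numeric(slope >= 0),
                score_sd = score_sd, cv = cv)
  lp <- rep(0, n)
  for (nm in names(config$betas))
    lp <- lp + config$betas[[nm]] * (terms[[nm]] - mean(terms[[nm]]))
  for (nm in names(config$covariate_betas)) {
    x <- cov[[nm]]
    if (is.factor(x)) x <- as.numeric(x) - 1
    lp <- lp + config$covariate_betas[[nm]] * (x - mean(x))
  }

  rate <- config$baseline_hazard * exp(lp)
  tev <- stats::rexp(n, rate)
  window_len <- times[w]
  if (mean(tev < window_len) > 0.99)
    stop("degenerate configuration: >99% of subjects fail inside the exposure window")
  cens <- rep(config$censor_time_years, n)
  if (config$dropout_rate > 0) {
    drop <- stats::runif(n) < config$dropout_rate
    cens[drop] <- stats::runif(sum(drop), 0.5, config$censor_time_years)
  }
  event <- as.integer(tev <= cens)
  time_years <- pmin(tev, cens)
  # first panel wave at or after the event time (NA once past the last wave:
  # ascertainment then happens at a post-window follow-up visit)
  event_wave <- ifelse(event == 1,
                       findInterval(tev, times + 1e-9) + 1L, NA_integer_)
  event_wave[event == 1 & event_wave > w] <- NA_integer_

  participants <- cbind(
    data.frame(id = seq_len(n)), cov,
    data.frame(cumds_true = cumds, cumads_true = cumads, lp_true = lp,
               time_years = time_years, event = event,
               event_wave = as.integer(event_wave)))

  panel <- data.frame(
    id = rep(seq_len(n), each = w),
    wave = rep(seq_len(w), n),
    time = rep(times, n),
    age = rep(cov$age, each = w) + rep(times, n),
    score = as.vector(t(S)))

  out <- list(participants = participants, panel = panel, scale = sc,
              config = config)
  class(out) <- "dep_cohort"
  out
}

#' @export
print.dep_cohort <- function(x, ...) {
  cat(sprintf("<dep_cohort> %d participants, %d waves (%s), %d events (%.1f%%)\n",
              nrow(x$participants), x$config$n_waves, x$scale$name,
              sum(x$participants$event),
              100 * mean(x$participants$event)))
  invisible(x)
}

#' Fill in cognition, ADL and self-report measures consistent with outcomes
#'
#' Adds per-wave cognitive domain scores (memory 0--20, orientation 0--4,
#' executive), ADL difficulty counts and a self-reported diagnosis flag to a
#' simulated cohort, constructed so the algorithmic dementia classifier
#' agrees with the generated survival outcome at the event wave: event
#' participants receive, from their event wave onward, a memory score 2.5 SD
#' below their education stratum's generating mean plus at least one ADL
#' difficulty (or, under the summary-score rule, a composite at or below the
#' cut); non-events are drawn truncated above 1.4 SD below the mean with no
#' planted dependency. The generating norms are attached as the `norms`
#' element so classifier tests can use the exact thresholds.
#'
#' @param cohort A `dep_cohort` from [simulate_cohort()].
#' @param rule `"concurrence"` (cognition + ADL) or `"summary_score"`
#'   (HRS-style composite).
#' @param noise_rate Fraction of non-events receiving borderline scores;
#'   default 0 (classification then recovers the planted outcome exactly).
#' @param self_report_rate Probability an event participant also carries a
#'   self-reported physician diagnosis at the event wave; default 0.
#' @return The cohort with cognition/ADL/self-report columns added to
#'   `$panel` and a `norms` data frame (education stratum x domain mean/SD).
#' @export
simulate_cognition_adl <- function(cohort, rule = c("concurrence", "summary_score"),
                                   noise_rate = 0, self_report_rate = 0) {
  stopifnot(inherits(cohort, "dep_cohort"))
  rule <- match.arg(rule)
  set.seed(cohort$config$seed + 104729L)  # independent stream, reproducible
  panel <- cohort$panel
  part <- cohort$participants
  w <- cohort$config$n_waves
  n <- nrow(part)

  edu_lev <- levels(part$education)
  norms <- expand.grid(education = edu_lev,
                       domain = c("memory", "orientation", "executive"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  norms$mean <- c(9.5, 10.5, 11.5,   # memory by stratum
                  3.2, 3.4, 3.6,     # orientation
                  3.0, 3.3, 3.6)     # executive
  norms$sd <- c(2.0, 2.0, 2.0, 0.45, 0.45, 0.45, 1.0, 1.0, 1.0)

  edu_idx <- as.integer(part$education)[panel$id]
  draw_domain <- function(domain) {
    mu <- norms$mean[match(paste(edu_lev[edu_idx], domain),
                           paste(norms$education, norms$domain))]
    sdv <- norms$sd[match(paste(edu_lev[edu_idx], domain),
                          paste(norms$education, norms$domain))]
    # truncated above mu - 1.4 sd: never crosses the 1.5-SD impairment line
    z <- stats::qnorm(stats::runif(nrow(panel), stats::pnorm(-1.4), 1))
    mu + sdv * z
  }
  panel$memory <- draw_domain("memory")
  panel$orientation <- pmin(draw_domain("orientation"), 4)
  panel$executive <- draw_domain("executive")
  panel$adl <- stats::rpois(nrow(panel), 0.1) *
    stats::rbinom(nrow(panel), 1, 0.15)
  panel$self_report <- FALSE

  if (noise_rate > 0) {
    # borderline (but still unimpaired) cognition for a random fraction
    fuzz <- stats::runif(nrow(panel)) < noise_rate
    panel$memory[fuzz] <- panel$memory[fuzz] - 0.2
  }

  ev <- which(part$event == 1 & !is.na(part$event_wave))
  for (i in ev) {
    rows <- which(panel$id == part$id[i] & panel$wave >= part$event_wave[i])
    mu <- norms$mean[norms$domain == "memory" &
                     norms$education == as.character(part$education[i])]
    sdv <- norms$sd[norms$domain == "memory" &
                    norms$education == as.character(part$education[i])]
    if (rule == "concurrence") {
      panel$memory[rows] <- mu - 2.5 * sdv
      panel$adl[rows] <- pmax(panel$adl[rows], 1L)
    } else {
      panel$memory[rows] <- 3
      panel$executive[rows] <- 2
    }
    if (self_report_rate > 0 && stats::runif(1) < self_report_rate)
      panel$self_report[rows] <- TRUE
  }
  panel$memory <- pmin(pmax(panel$memory, 0), 20)
  panel$orientation <- pmin(pmax(panel$orientation, 0), 4)
  panel$executive <- pmax(panel$executive, 0)

  cohort$panel <- panel
  cohort$norms <- norms
  cohort
}
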