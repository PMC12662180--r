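#' Validate a panel with the sequential exclusion cascade
#'
#' Applies the standard exclusion cascade in fixed order and reports the
#' count removed at each step: (1) missing sociodemographic information;
#' (2) age below the cohort threshold; (3) prevalent dementia at baseline;
#' (4) loss to follow-up (missing outcome); (5) incomplete symptom,
#' cognitive or functional assessments.
#'
#' @param participants Participant-level data frame (covariates, outcome).
#' @param panel Long panel (wave-level scores and, optionally, cognition).
#' @param classification Optional `dementia_classification`; used for the
#'   prevalent-dementia step (participants positive at wave 1).
#' @param age_threshold Minimum baseline age (default 50; 45 for
#'   SHARE/CHARLS-style designs).
#' @return List with `counts` (named integer vector per step), `kept_ids`,
#'   `participants` and `panel` restricted to the analytic sample.
#' @export
validate_panel <- function(participants, panel, classification = NULL,
                           age_threshold = 50) {
  counts <- c(missing_sociodemographics = 0L, below_age_threshold = 0L,
              prevalent_dementia = 0L, loss_to_follow_up = 0L,
              incomplete_assessments = 0L)
  keep <- participants

  socio <- intersect(c("age", "gender", "marital", "education", "residence"),
                     names(keep))
  bad <- !stats::complete.cases(keep[socio])
  counts["missing_sociodemographics"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]

  bad <- keep$age < age_threshold
  counts["below_age_threshold"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]

  if (!is.null(classification)) {
    prev <- classification$id[!is.na(classification$first_positive_wave) &
                              classification$first_positive_wave == 1L]
    bad <- keep$id %in% prev
    counts["prevalent_dementia"] <- sum(bad)
    keep <- keep[!bad, , drop = FALSE]
  }

  bad <- is.na(keep$time_years) | is.na(keep$event)
  counts["loss_to_follow_up"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]

  score_ok <- tapply(panel$score, panel$id, function(s) !anyNA(s))
  complete_ids <- names(score_ok)[score_ok]
  bad <- !(as.character(keep$id) %in% complete_ids)
  counts["incomplete_assessments"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]

  list(counts = counts, kept_ids = keep$id,
       participants = keep,
       panel = panel[panel$id %in% keep$id, , drop = FALSE])
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(stage, n_in, n_out, quiet) {
  if (!quiet)
    message(sprintf("[%s] rows in: %d, rows out: %d", stage, n_in, n_out))
}

#' Run the full analysis pipeline on a simulated or supplied cohort
#'
#' Orchestrates simulate -> classify -> validate -> derive exposures ->
#' variability/VIM calibration -> cutoff -> Cox model ladder -> trend tests
#' -> Kaplan-Meier -> spline, writing CSV artifacts and a run-metadata JSON
#' (seed, cutoff, config hash, stage row counts) when `outdir` is given.
#' Re-running with an identical configuration reproduces all numbers.
#'
#' @param config A list (or path to a YAML/JSON file) with components:
#'   `simulation` (arguments for [sim_config()]), `cutoff_source`
#'   (`"screening"`, `"search"` or `"fixed"`), `fixed_cutoff` (when fixed),
#'   `duration_window`, `min_group_fraction`, `models` (subset of M1--M4),
#'   `age_threshold`, `lagged` (logical), `outdir` (optional).
#' @param quiet Suppress stage logging.
#' @return Invisible list with every stage product: `cohort`,
#'   `validation`, `classification`, `exposures`, `variability`, `cutpoint`,
#'   `fits` (per exposure coding x model), `trend`, `km`, `spline`,
#'   `metadata`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(cutoff_source = "search", fixed_cutoff = NULL,
                   duration_window = c(1L, 2L), min_group_fraction = 0.10,
                   models = "M4", age_threshold = 50, lagged = FALSE,
                   outdir = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$simulation))
    stop("config must contain a `simulation` block")
  hash <- config_hash(config)

  sim_cfg <- do.call(sim_config, config$simulation)
  cohort <- simulate_cohort(sim_cfg)
  cohort <- simulate_cognition_adl(cohort)
  stage_log("simulate", sim_cfg$n_participants, nrow(cohort$participants), quiet)

  norms <- compute_norms(cohort$panel, cohort$participants)
  cls <- classify_dementia(cohort$panel, cohort$participants, norms)
  stage_log("classify", nrow(cohort$participants),
            sum(!is.na(cls$first_positive_wave)), quiet)

  val <- validate_panel(cohort$participants, cohort$panel,
                        classification = cls,
                        age_threshold = config$age_threshold)
  part <- val$participants
  part$first_positive_wave <-
    cls$first_positive_wave[match(part$id, cls$id)]
  if (isTRUE(config$lagged)) {
    part <- lagged_exclusion(part)
    stage_log("lagged_exclusion", length(val$kept_ids), nrow(part), quiet)
  }
  panel <- val$panel[val$panel$id %in% part$id, , drop = FALSE]
  stage_log("validate", nrow(cohort$participants), nrow(part), quiet)

  scale <- cohort$scale
  cutpoint <- NULL
  cutoff <- switch(config$cutoff_source,
    screening = scale$high_threshold,
    fixed = {
      if (is.null(config$fixed_cutoff)) stop("fixed cutoff not supplied")
      config$fixed_cutoff
    },
    search = {
      sc <- panel$score
      per_id <- data.frame(id = panel$id, score = panel$score)
      out <- merge(per_id, part[c("id", "time_years", "event")], by = "id")
      cutpoint <- optimal_cutoff(out$score, out$time_years, out$event,
                                 config$min_group_fraction)
      cutpoint$cutoff
    },
    stop("cutoff_source must be screening, search or fixed"))
  stage_log("cutoff", nrow(panel), 1L, quiet)

  expo <- derive_exposures(panel, cutoff = cutoff,
                           duration_window = config$duration_window)
  vvv <- add_variability(panel)
  dat <- merge(part, expo, by = "id")
  dat <- merge(dat, vvv, by = "id")
  stage_log("derive", nrow(part), nrow(dat), quiet)

  q_cumds <- assign_quartiles(dat$cumds)
  dat$cumds_quartile <- factor(q_cumds$labels, levels = 1:4,
                               labels = paste0("Q", 1:4))
  dat$cumads_z <- zstandardize(dat$cumads)

  codings <- list(cumds = "cumds", cumads = "cumads",
                  quartile = "cumds_quartile", burden = "burden_class",
                  duration = "factor(duration_years)",
                  slope = "slope_class", pattern = "pattern",
                  sd = "score_sd", cv = "cv", vim = "vim",
                  zscore = "cumads_z")
  dat$duration_cat <- factor(dat$duration_years, levels = c(0, 2, 4),
                             labels = c("0y", "2y", "4y"))
  codings$duration <- "duration_cat"

  fits <- list()
  for (m in config$models) {
    fits[[m]] <- list()
    for (cd in names(codings)) {
      fits[[m]][[cd]] <- tryCatch(
        suppressWarnings(fit_cox(dat, codings[[cd]], model = m)),
        error = function(e) e$message)
    }
  }
  stage_log("fit", nrow(dat), length(config$models) * length(codings), quiet)

  trend <- tryCatch(trend_test(dat, q_cumds, model = config$models[[1]]),
                    error = function(e) e$message)
  km <- km_estimate(dat, dat$cumds_quartile)
  spline <- tryCatch(rcs_fit(dat, "cumads", model = config$models[[1]]),
                     error = function(e) e$message)

  metadata <- list(config_hash = hash, seed = sim_cfg$seed,
                   scale = scale$name, cutoff = cutoff,
                   cutoff_source = config$cutoff_source,
                   duration_window = config$duration_window,
                   ties = "efron", time_origin = "baseline",
                   vim_beta = attr(vvv, "calibration")$beta,
                   exclusions = as.list(val$counts),
                   n_analytic = nrow(dat), events = sum(dat$event))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(x, file.path(config$outdir, f),
                                          row.names = FALSE)
    wr(expo, "exposures.csv")
    wr(vvv, "variability.csv")
    if (!is.null(cutpoint)) wr(cutpoint$grid, "cutpoint_grid.csv")
    rows <- list()
    for (m in names(fits)) for (cd in names(fits[[m]])) {
      f <- fits[[m]][[cd]]
      if (inherits(f, "dep_coxfit")) {
        tb <- f$table; tb$model <- m; tb$coding <- cd
        rows[[paste(m, cd)]] <- tb
      }
    }
    wr(do.call(rbind, rows), "cox_models.csv")
    if (inherits(spline, "dep_splinefit")) wr(spline$curve, "spline_curve.csv")
    wr(km$table, "km_curves.csv")
    writeLines(jsonlite::toJSON(metadata, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(config$outdir, "run_metadata.json"))
  }

  invisible(list(cohort = cohort, validation = val, classification = cls,
                 exposures = expo, variability = vvv, cutpoint = cutpoint,
                 data = dat, fits = fits, trend = trend, km = km,
                 spline = spline, metadata = metadata))
}
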