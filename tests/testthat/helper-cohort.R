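# shared fixtures, all generated in code

# tiny deterministic survival dataset: two groups with well-separated
# event times, no censoring
toy_surv <- function() {
  data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
             group = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
}

quick_cohort <- function(n = 1000, betas = list(), scale = "CESD8",
                         seed = 1, ...) {
  simulate_cohort(sim_config(n, scale = scale, betas = betas, seed = seed, ...))
}

# participant data with derived exposures merged on, ready for fit_cox
cohort_data <- function(cohort, cutoff = cohort$scale$high_threshold) {
  ex <- derive_exposures(cohort, cutoff = cutoff)
  merge(cohort$participants, ex, by = "id")
}
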