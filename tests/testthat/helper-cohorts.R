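## Shared fixtures: tiny hand-built cohorts with known biopsy layouts, and
## cached simulated cohorts reused across tests.

## Build an as_cohort directly from per-subject biopsy times/results and a
## covariate value table; covariates default to zero at every landmark.
toy_cohort <- function(times, results, config = scenario_config(),
                       covariates = NULL, truth = NULL) {
  n <- length(times)
  len <- lengths(times)
  biopsies <- data.frame(id = rep(seq_len(n), len),
                         time = unlist(times, use.names = FALSE),
                         result = as.integer(unlist(results, use.names = FALSE)))
  if (is.null(covariates)) {
    lm_id <- rep(seq_len(n), times = length(config$landmarks))
    lm_t <- rep(config$landmarks, each = n)
    Z <- matrix(0, length(lm_id), config$p,
                dimnames = list(NULL, paste0("z", seq_len(config$p))))
    covariates <- data.frame(id = lm_id, time = lm_t, Z)
  }
  tailoras:::new_cohort(biopsies, covariates, truth, config,
                        seed = NA_integer_, n = n)
}

## Cache moderately expensive simulated cohorts within a test run.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed, config = scenario_config(1), ...) {
  key <- paste(n, seed, config$scenario, config$T_gap, sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(n, config, seed = seed, ...)
  }
  .cohort_cache[[key]]
}

## Reference linear rule aligned with the simulated hazard (higher risk ->
## biopsy): f(Z) = -0.7 z2 + 0.8 z3 - 1.3 z4.
reference_rule <- function() linear_rule(c(0, -0.7, 0.8, -1.3), 0)

## Monte-Carlo truth helper: marginal event-time draws at scale `n`.
mc_event_times <- function(n, config = scenario_config(1), seed = 424243) {
  old <- globalenv()$.Random.seed
  on.exit(tailoras:::restore_rng(old), add = TRUE)
  set.seed(seed)
  tailoras:::draw_latents(n, config)$T_true
}
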