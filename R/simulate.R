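#' Configuration of the simulated active-surveillance study
#'
#' Collects every constant of the generative model used in the simulation
#' studies: latent linear-in-log-time covariate trajectories with Gaussian
#' measurement error, a Weibull-type progression time with linear (and, in
#' Scenario 2, quadratic) covariate effects, uniform loss to follow-up on
#' [12, 150] months, random biopsy schedules with a minimum gap, and
#' immediate dropout after the first observed positive biopsy.
#'
#' @param scenario 1 (linear log-hazard) or 2 (adds a quadratic term with
#'   coefficient `r_nl = 0.1`).
#' @param p number of covariate processes; the progression hazard loads on
#'   processes 2..4, process 1 is pure noise available to the learner.
#' @param slope_mean,slope_cov mean and covariance of each bivariate-normal
#'   (intercept, slope) pair of a latent trajectory
#'   W_l(t) = a0_l + a1_l log(t / nu).
#' @param meas_var variance of the Gaussian measurement error added to each
#'   observed covariate value X_l(t) = W_l(t) + eps.
#' @param beta log-hazard coefficients applied to the trajectories of
#'   processes 2..4.
#' @param r_nl coefficient of the quadratic term (a_{.,1} + a_{.,2})^2;
#'   0 under Scenario 1, 0.1 under Scenario 2.
#' @param nu time scale (months) of the log-time trajectories.
#' @param nu_scale,nu_shape scale and shape constants of the baseline hazard.
#' @param entry_offset months added to the transformed exponential draw; the
#'   progression time is `entry_offset` plus a positive quantity.
#' @param censor_lo,censor_hi support of the uniform censoring time (months).
#' @param horizon administrative end of the biopsy schedule (months).
#' @param T_gap minimum gap between consecutive scheduled biopsies (months);
#'   consecutive gaps are uniform on [T_gap, 3 T_gap].
#' @param miss_prob per-biopsy probability of a missed appointment.
#' @param landmarks decision landmark times t_j (months) at which covariates
#'   are measured and rules are applied.
#' @param tau months between a decision landmark and the biopsy it schedules.
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(scenario = 1,
                            p = 4,
                            slope_mean = c(-0.1, -0.1),
                            slope_cov = matrix(c(0.82^2, -0.005,
                                                 -0.005, 0.13^2), 2, 2),
                            meas_var = 0.1,
                            beta = c(-0.7, 0.8, -1.3),
                            r_nl = if (scenario == 1) 0 else 0.1,
                            nu = 30,
                            nu_scale = 15,
                            nu_shape = 1.4,
                            entry_offset = 12,
                            censor_lo = 12,
                            censor_hi = 150,
                            horizon = 150,
                            T_gap = 24,
                            miss_prob = 0,
                            landmarks = c(24, 48, 72, 96),
                            tau = 24) {
  stopifnot(scenario %in% c(1, 2),
            p >= length(beta) + 1,
            length(slope_mean) == 2,
            is.matrix(slope_cov), all(dim(slope_cov) == 2),
            meas_var >= 0,
            nu_shape > 0,
            censor_lo < censor_hi,
            T_gap > 0,
            miss_prob >= 0, miss_prob < 1,
            tau > 0,
            all(landmarks > 0))
  if (max(abs(slope_cov - t(slope_cov))) > 1e-12 ||
      any(eigen(slope_cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("'slope_cov' must be symmetric positive definite")
  }
  structure(list(scenario = scenario, p = p, slope_mean = slope_mean,
                 slope_cov = slope_cov, meas_var = meas_var, beta = beta,
                 r_nl = r_nl, nu = nu, nu_scale = nu_scale,
                 nu_shape = nu_shape, entry_offset = entry_offset,
                 censor_lo = censor_lo, censor_hi = censor_hi,
                 horizon = horizon, T_gap = T_gap, miss_prob = miss_prob,
                 landmarks = landmarks, tau = tau),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Active-surveillance simulation scenario", x$scenario, "\n")
  cat("  covariate processes:", x$p,
      "| hazard coefficients on z2..z4:", paste(x$beta, collapse = ", "), "\n")
  cat("  quadratic coefficient r_nl:", x$r_nl, "\n")
  cat("  censoring U[", x$censor_lo, ",", x$censor_hi,
      "] | biopsy gap T_gap:", x$T_gap,
      "| missed-biopsy prob:", x$miss_prob, "\n")
  cat("  landmarks:", paste(x$landmarks, collapse = ", "),
      "| tau:", x$tau, "months\n")
  invisible(x)
}

## Linear predictors of the progression-time transform.
## eta0 drives the scale, gamma the shape of the Weibull-type event time.
latent_eta0 <- function(a0, config) {
  idx <- seq_along(config$beta) + 1L
  drop(a0[, idx, drop = FALSE] %*% config$beta) +
    config$r_nl * (a0[, 1] + a0[, 2])^2
}

latent_gamma <- function(a1, config) {
  idx <- seq_along(config$beta) + 1L
  config$nu_shape + drop(a1[, idx, drop = FALSE] %*% config$beta) +
    config$r_nl * (a1[, 1] + a1[, 2])^2
}

## Progression time from the closed-form transform of a standard exponential.
event_time_from_exp <- function(ttilde, a0, a1, config) {
  gamma <- latent_gamma(a1, config)
  eta0 <- latent_eta0(a0, config)
  config$entry_offset +
    config$nu * (ttilde * gamma / config$nu_shape * exp(-eta0))^(1 / gamma)
}

## Vectorised draw of n latent subjects: (a0, a1) trajectory coefficients for
## all p processes, progression time T_true and censoring time C. Subjects
## whose shape parameter gamma is <= 1e-3 (the closed form degenerates) are
## resampled; after 100 rounds the configuration is declared degenerate.
draw_latents <- function(n, config) {
  p <- config$p
  R <- chol(config$slope_cov)
  draw_block <- function(m) {
    a0 <- matrix(0, m, p)
    a1 <- matrix(0, m, p)
    for (l in seq_len(p)) {
      z <- matrix(stats::rnorm(2 * m), m, 2) %*% R
      a0[, l] <- config$slope_mean[1] + z[, 1]
      a1[, l] <- config$slope_mean[2] + z[, 2]
    }
    list(a0 = a0, a1 = a1)
  }
  b <- draw_block(n)
  gamma <- latent_gamma(b$a1, config)
  tries <- 0L
  while (any(bad <- gamma <= 1e-3)) {
    tries <- tries + 1L
    if (tries > 100L) {
      stop("degenerate configuration: gamma <= 1e-3 persists after 100 resampling rounds")
    }
    nb <- draw_block(sum(bad))
    b$a0[bad, ] <- nb$a0
    b$a1[bad, ] <- nb$a1
    gamma[bad] <- latent_gamma(nb$a1, config)
  }
  ttilde <- stats::rexp(n)
  T_true <- event_time_from_exp(ttilde, b$a0, b$a1, config)
  C <- stats::runif(n, config$censor_lo, config$censor_hi)
  list(a0 = b$a0, a1 = b$a1, T_true = T_true, C = C)
}

#' Draw one latent subject
#'
#' Draws the (intercept, slope) pair of each covariate trajectory from a
#' bivariate normal, the progression time from the closed-form transform of a
#' standard exponential, and a uniform censoring time. Exposed mainly for
#' inspection and testing; [simulate_cohort()] draws whole cohorts at once.
#'
#' @param config a [scenario_config()].
#' @return List with matrices `a0`, `a1` (1 x p), `T_true` and `C` (months).
#' @export
draw_subject <- function(config) {
  l <- draw_latents(1L, config)
  list(a0 = l$a0, a1 = l$a1, T_true = l$T_true, C = l$C)
}

#' Latent or observed covariate value
#'
#' W_l(t) = a0_l + a1_l log(t / nu); the observed value adds fresh Gaussian
#' measurement noise with variance `meas_var`.
#'
#' @param latent list with `a0`, `a1` matrices as returned by
#'   [draw_subject()] (rows = subjects).
#' @param l covariate process index.
#' @param t time in months (> 0).
#' @param config a [scenario_config()].
#' @param with_noise add measurement error?
#' @return Numeric vector, one value per subject row in `latent`.
#' @export
covariate_value <- function(latent, l, t, config, with_noise = FALSE) {
  if (any(t <= 0)) stop("'t' must be positive (trajectories are log-time)")
  w <- latent$a0[, l] + latent$a1[, l] * log(t / config$nu)
  if (with_noise && config$meas_var > 0) {
    w <- w + stats::rnorm(length(w), 0, sqrt(config$meas_var))
  }
  w
}

#' Random biopsy schedule
#'
#' The first biopsy is uniform on [entry_offset, 3 T_gap]; each later biopsy
#' falls uniformly in [previous + T_gap, previous + 3 T_gap]; scheduling stops
#' once previous + T_gap exceeds the horizon.
#'
#' @param config a [scenario_config()].
#' @return Increasing numeric vector of scheduled biopsy times (months).
#' @export
draw_biopsy_schedule <- function(config) {
  times <- stats::runif(1, config$entry_offset, 3 * config$T_gap)
  while (times[length(times)] + config$T_gap <= config$horizon) {
    last <- times[length(times)]
    times <- c(times, stats::runif(1, last + config$T_gap, last + 3 * config$T_gap))
  }
  times
}

#' Observed biopsy sequence of one subject
#'
#' Walks a schedule in order and applies, in this order, terminal censoring
#' (a biopsy at or after the censoring time ends follow-up), per-biopsy
#' missingness, and immediate dropout after the first retained positive
#' result.
#'
#' @param T_true,C progression and censoring times (months); `C = Inf`
#'   disables censoring.
#' @param schedule increasing vector of scheduled biopsy times.
#' @param config a [scenario_config()] (supplies `miss_prob`).
#' @param miss optional logical vector, same length as `schedule`: TRUE marks
#'   a missed appointment. When NULL and `miss_prob > 0`, missingness is
#'   drawn Bernoulli(miss_prob).
#' @param dropout keep observing after a positive biopsy? Default TRUE
#'   (immediate dropout, the surveillance-study behaviour); FALSE yields the
#'   panel current-status regime used to validate the current-status baseline.
#' @return List with `times`, `results` (0/1) of retained biopsies and
#'   `dropped_out` flag.
#' @export
assemble_observed <- function(T_true, C, schedule, config,
                              miss = NULL, dropout = TRUE) {
  if (is.unsorted(schedule, strictly = TRUE)) {
    stop("'schedule' must be strictly increasing")
  }
  if (is.null(miss)) {
    miss <- if (config$miss_prob > 0) {
      stats::runif(length(schedule)) < config$miss_prob
    } else rep(FALSE, length(schedule))
  }
  times <- numeric(0)
  results <- integer(0)
  dropped <- FALSE
  for (k in seq_along(schedule)) {
    nk <- schedule[k]
    if (C <= nk) break            # censoring is terminal
    if (miss[k]) next             # missed appointment: this biopsy only
    dk <- as.integer(T_true <= nk)
    times <- c(times, nk)
    results <- c(results, dk)
    if (dk == 1L && dropout) {
      dropped <- TRUE
      break
    }
  }
  list(times = times, results = results, dropped_out = dropped)
}

## Internal cohort constructor: derives the adjacent-pair table (with the
## confirmatory baseline biopsy N_0 = 0, result 0) and per-subject summaries.
new_cohort <- function(biopsies, covariates, truth, config, seed, n,
                       dropout = TRUE) {
  ids <- seq_len(n)
  has <- tabulate(biopsies$id, nbins = n) > 0
  last_obs <- numeric(n)
  if (nrow(biopsies) > 0) {
    mx <- tapply(biopsies$time, factor(biopsies$id, levels = ids), max)
    last_obs[has] <- mx[has]
  }
  ## adjacent observed pairs: prepend the baseline biopsy at time 0
  if (nrow(biopsies) > 0) {
    ord <- order(biopsies$id, biopsies$time)
    b <- biopsies[ord, , drop = FALSE]
    first <- !duplicated(b$id)
    t_prev <- c(0, b$time[-nrow(b)])
    r_prev <- c(0L, b$result[-nrow(b)])
    t_prev[first] <- 0
    r_prev[first] <- 0L
    pairs <- data.frame(id = b$id, t_prev = t_prev, t_curr = b$time,
                        res_prev = r_prev, res_curr = b$result)
  } else {
    pairs <- data.frame(id = integer(0), t_prev = numeric(0),
                        t_curr = numeric(0), res_prev = integer(0),
                        res_curr = integer(0))
  }
  structure(list(biopsies = biopsies, covariates = covariates, truth = truth,
                 pairs = pairs, last_obs = last_obs, n = n, p = config$p,
                 config = config, seed = seed, dropout = dropout,
                 cache = new.env(parent = emptyenv())),
            class = "as_cohort")
}

#' Simulate a surveillance cohort
#'
#' Generates `n` independent subjects under the configured scenario and
#' returns the observed data (retained biopsy times and results, noisy
#' covariate measurements at every retained biopsy time and at every decision
#' landmark) together with the latent truth (progression and censoring times)
#' for oracle evaluation. The result is a pure function of
#' `(n, config, seed)`.
#'
#' @param n number of subjects.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @param schedule optional fixed biopsy schedule applied to every subject
#'   (replaces the random schedule; used for design checks).
#' @param censoring draw uniform censoring times? FALSE sets C = Inf.
#' @param dropout immediate dropout after the first positive biopsy
#'   (default TRUE); see [assemble_observed()].
#' @return An object of class `as_cohort`: a list with elements `biopsies`
#'   (id, time, result), `covariates` (id, time, z1..zp), `pairs` (adjacent
#'   observed biopsy pairs including the baseline at time 0), `truth`
#'   (id, T, C), `last_obs`, `n`, `config`, `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(50, scenario_config(1), seed = 1)
#' coh
simulate_cohort <- function(n, config, seed, schedule = NULL,
                            censoring = TRUE, dropout = TRUE) {
  stopifnot(n >= 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  lat <- draw_latents(n, config)
  if (!censoring) lat$C <- rep(Inf, n)

  obs_times <- vector("list", n)
  obs_res <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- if (is.null(schedule)) draw_biopsy_schedule(config) else schedule
    o <- assemble_observed(lat$T_true[i], lat$C[i], sched, config,
                           dropout = dropout)
    obs_times[[i]] <- o$times
    obs_res[[i]] <- o$results
  }
  len <- lengths(obs_times)
  biopsies <- data.frame(id = rep(seq_len(n), len),
                         time = unlist(obs_times, use.names = FALSE),
                         result = as.integer(unlist(obs_res, use.names = FALSE)))
  if (nrow(biopsies) == 0) {
    biopsies <- data.frame(id = integer(0), time = numeric(0),
                           result = integer(0))
  }

  ## noisy covariates at landmark times (all subjects) and at retained
  ## biopsy times
  lm_id <- rep(seq_len(n), times = length(config$landmarks))
  lm_t <- rep(config$landmarks, each = n)
  cov_id <- c(lm_id, biopsies$id)
  cov_t <- c(lm_t, biopsies$time)
  Z <- matrix(0, length(cov_id), config$p)
  for (l in seq_len(config$p)) {
    w <- lat$a0[cov_id, l] + lat$a1[cov_id, l] * log(cov_t / config$nu)
    if (config$meas_var > 0) {
      w <- w + stats::rnorm(length(w), 0, sqrt(config$meas_var))
    }
    Z[, l] <- w
  }
  colnames(Z) <- paste0("z", seq_len(config$p))
  covariates <- data.frame(id = cov_id, time = cov_t, Z)

  truth <- data.frame(id = seq_len(n), T = lat$T_true, C = lat$C)
  truth$a0 <- lat$a0
  truth$a1 <- lat$a1
  new_cohort(biopsies, covariates, truth, config, seed, n, dropout = dropout)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.as_cohort <- function(x, ...) {
  npos <- sum(x$biopsies$result == 1)
  cat("Surveillance cohort:", x$n, "subjects,",
      nrow(x$biopsies), "observed biopsies (", npos, "positive )\n")
  cat("  scenario", x$config$scenario, "| T_gap", x$config$T_gap,
      "| seed", x$seed, if (!is.null(x$truth)) "| truth retained", "\n")
  invisible(x)
}

#' Subset a cohort by subject ids
#'
#' Used for subject-level cross-validation folds. Subject ids are renumbered
#' 1..length(ids) in the returned cohort.
#'
#' @param cohort an `as_cohort`.
#' @param ids subject ids to keep.
#' @return An `as_cohort` with the selected subjects.
#' @export
subset_cohort <- function(cohort, ids) {
  ids <- sort(unique(ids))
  remap <- match(seq_len(cohort$n), ids)   # old id -> new id (NA dropped)
  sel_b <- cohort$biopsies$id %in% ids
  b <- cohort$biopsies[sel_b, , drop = FALSE]
  b$id <- remap[b$id]
  sel_c <- cohort$covariates$id %in% ids
  cv <- cohort$covariates[sel_c, , drop = FALSE]
  cv$id <- remap[cv$id]
  tr <- if (is.null(cohort$truth)) NULL else {
    t2 <- cohort$truth[cohort$truth$id %in% ids, , drop = FALSE]
    t2$id <- remap[t2$id]
    t2[order(t2$id), , drop = FALSE]
  }
  new_cohort(b, cv, tr, cohort$config, cohort$seed, length(ids),
             dropout = cohort$dropout)
}

#' Covariate matrix at a decision landmark
#'
#' @param cohort an `as_cohort`.
#' @param s landmark time; must be one of the measurement times stored in the
#'   cohort's covariate table for every subject.
#' @return n x p numeric matrix (rows ordered by subject id).
#' @export
landmark_covariates <- function(cohort, s) {
  cv <- cohort$covariates
  sel <- cv$time == s
  if (sum(sel) < cohort$n) {
    stop("no covariate measurements at landmark s = ", s,
         " for every subject; landmarks must be in the cohort's grid")
  }
  sub <- cv[sel, , drop = FALSE]
  sub <- sub[!duplicated(sub$id), , drop = FALSE]
  sub <- sub[order(sub$id), , drop = FALSE]
  as.matrix(sub[, paste0("z", seq_len(cohort$p)), drop = FALSE])
}
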