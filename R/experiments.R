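#' Oracle performance of a rule from retained truth
#'
#' Computes TPR, TNR, rho and the weighted-benefits value of a rule on a
#' truth-bearing cohort using the true progression times (no censoring, no
#' interval censoring): the gold standard against which the estimators are
#' judged.
#'
#' @param cohort an `as_cohort` with `truth`.
#' @param rule a decision rule.
#' @param landmarks decision landmark times.
#' @param tau decision horizon.
#' @param r optional cost-benefit ratio; when given, the value uses
#'   xi(t_j) = (1 - rho_j) / (rho_j r) with rho_j the empirical truth;
#'   otherwise xi = 1 at every landmark.
#' @return data.frame with one row per landmark (s, tpr, tnr, rho, xi,
#'   value_term) plus attribute `value`, the landmark average.
#' @export
oracle_performance <- function(cohort, rule,
                               landmarks = cohort$config$landmarks,
                               tau = cohort$config$tau, r = NULL) {
  if (is.null(cohort$truth)) stop("cohort carries no truth")
  Tt <- cohort$truth$T[order(cohort$truth$id)]
  out <- lapply(landmarks, function(s) {
    d <- rule_decide(rule, landmark_covariates(cohort, s))
    case <- Tt > s & Tt <= s + tau
    ctrl <- Tt > s + tau
    atrisk <- Tt > s
    rho <- if (any(atrisk)) mean(case) / mean(atrisk) else NA_real_
    xi <- if (is.null(r)) 1 else {
      if (is.na(rho) || rho <= 0 || rho >= 1) NA_real_ else xi_from_rho(rho, r)
    }
    tpr <- if (any(case)) mean(d[case] == 1L) else NA_real_
    tnr <- if (any(ctrl)) mean(d[ctrl] == -1L) else NA_real_
    data.frame(s = s, tau = tau, tpr = tpr, tnr = tnr, rho = rho, xi = xi,
               value_term = tpr + xi * tnr)
  })
  out <- do.call(rbind, out)
  attr(out, "value") <- mean(out$value_term, na.rm = TRUE)
  out
}

#' Configuration of a simulation study
#'
#' Collects the experimental factors of the estimator-comparison and
#' policy-comparison studies: scenario, sample sizes, biopsy gap, trade-off
#' grid, landmark grid and replicate count.
#'
#' @param scenario simulation scenario (1 or 2).
#' @param n_train training-cohort size for rule fitting.
#' @param n_eval evaluation-cohort size (estimator study).
#' @param n_test independent truth-bearing test-cohort size (policy study).
#' @param T_gap_train,T_gap_eval biopsy gaps for training / evaluation.
#' @param r_train cost-benefit ratio used to pretrain the reference rule.
#' @param r_grid cost-benefit ratios compared in the policy study.
#' @param landmarks,tau decision grid.
#' @param n_rep replicate count.
#' @param seed base seed; replicate i uses seed + i, the pretraining cohort
#'   uses seed itself.
#' @param lambda learner ridge penalty used throughout.
#' @param C_b bandwidth constant; defaults to twice the evaluation biopsy
#'   gap, so the kernel windows scale with the design's time resolution.
#' @param ref_rule reference rule for the estimator study: `"osf_i"`
#'   (pretrained interval-censoring-aware rule), `"osf_ipcw"` (pretrained
#'   IPCW-weighted rule, the right-censoring analogue), or a fixed rule
#'   object.
#' @return A `study_config` list.
#' @export
study_config <- function(scenario = 1, n_train = 500, n_eval = 500,
                         n_test = 1000,
                         T_gap_train = 24, T_gap_eval = 24, r_train = 3,
                         r_grid = c(2, 4, 8),
                         landmarks = c(24, 48, 72, 96), tau = 24,
                         n_rep = 100, seed = 2025,
                         lambda = 0.01, C_b = 2 * T_gap_eval,
                         ref_rule = "osf_i") {
  stopifnot(n_rep >= 1)
  structure(list(scenario = scenario, n_train = n_train, n_eval = n_eval,
                 n_test = n_test, T_gap_train = T_gap_train,
                 T_gap_eval = T_gap_eval, r_train = r_train, r_grid = r_grid,
                 landmarks = landmarks, tau = tau, n_rep = n_rep, seed = seed,
                 lambda = lambda, C_b = C_b, ref_rule = ref_rule),
            class = "study_config")
}

study_scenario_config <- function(config, T_gap) {
  scenario_config(scenario = config$scenario, T_gap = T_gap,
                  landmarks = config$landmarks, tau = config$tau)
}

#' Estimator-comparison study
#'
#' Pretrains a reference rule once (OSF-I on a training cohort), then, per
#' replicate, simulates an evaluation cohort and records the kernel (KR-I),
#' IPCW and current-status (KR-CS) TPR / TNR estimates at every landmark
#' next to the oracle values computed from truth.
#'
#' @param config a [study_config()].
#' @param verbose log one line per replicate to stderr.
#' @return Tidy data.frame: method, scenario, n, T_gap, replicate, seed,
#'   landmark, metric (tpr / tnr), value.
#' @export
run_estimator_study <- function(config = study_config(), verbose = FALSE) {
  rule <- if (!is.character(config$ref_rule)) {
    config$ref_rule
  } else {
    train <- simulate_cohort(config$n_train,
                             study_scenario_config(config, config$T_gap_train),
                             seed = config$seed)
    switch(config$ref_rule,
           osf_i = suppressWarnings(
             osf_i(train, r = config$r_train, lambda = config$lambda,
                   C_b = 2 * config$T_gap_train)),
           osf_ipcw = suppressWarnings(
             osf_ipcw(train, r = config$r_train, lambda = config$lambda)),
           stop("unknown ref_rule: ", config$ref_rule))
  }
  rows <- list()
  for (i in seq_len(config$n_rep)) {
    seed_i <- config$seed + i
    coh <- simulate_cohort(config$n_eval,
                           study_scenario_config(config, config$T_gap_eval),
                           seed = seed_i)
    bw <- bandwidths(config$C_b, coh$n)
    orc <- oracle_performance(coh, rule, config$landmarks, config$tau)
    for (j in seq_along(config$landmarks)) {
      s <- config$landmarks[j]
      est <- list(
        `KR-I` = c(
          tpr = tryCatch(estimate_tpr(coh, rule, s, config$tau, bw$h_tilde),
                         noSupportError = function(e) NA_real_),
          tnr = tryCatch(
            suppressWarnings(estimate_tnr(coh, rule, s, config$tau, bw$h)),
            noSupportError = function(e) NA_real_)),
        IPCW = {
          x <- ipcw_tpr_tnr(coh, rule, s, config$tau)
          c(tpr = x$tpr, tnr = x$tnr)
        },
        `KR-CS` = {
          x <- tryCatch(kr_cs_tpr_tnr(coh, rule, s, config$tau, bw$h),
                        noSupportError = function(e)
                          data.frame(tpr = NA_real_, tnr = NA_real_))
          c(tpr = x$tpr, tnr = x$tnr)
        },
        Oracle = c(tpr = orc$tpr[j], tnr = orc$tnr[j]))
      for (m in names(est)) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, scenario = config$scenario, n = config$n_eval,
          T_gap = config$T_gap_eval, replicate = i, seed = seed_i,
          landmark = s, metric = c("tpr", "tnr"),
          value = as.numeric(est[[m]][c("tpr", "tnr")]))
      }
    }
    if (verbose) message(sprintf("estimator study: replicate %d/%d (seed %d)",
                                 i, config$n_rep, seed_i))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Policy-comparison study
#'
#' Per replicate and per cost-benefit ratio r: fits the interval-censoring-
#' aware learner (OSF-I) and the IPCW-weighted comparator on a training
#' cohort, then evaluates both rules on an independent truth-bearing test
#' cohort (oracle TPR, TNR, value with the empirical-truth xi).
#'
#' @inheritParams run_estimator_study
#' @return Tidy data.frame: method, scenario, n, T_gap, r, replicate, seed,
#'   oracle_tpr, oracle_tnr, oracle_value (landmark averages).
#' @export
run_policy_study <- function(config = study_config(n_rep = 50), verbose = FALSE) {
  rows <- list()
  for (i in seq_len(config$n_rep)) {
    seed_i <- config$seed + i
    cfg <- study_scenario_config(config, config$T_gap_train)
    train <- simulate_cohort(config$n_train, cfg, seed = seed_i)
    test <- simulate_cohort(config$n_test, cfg, seed = seed_i + 500000L)
    for (r in config$r_grid) {
      fits <- list(
        `OSF-I` = tryCatch(
          suppressWarnings(osf_i(train, r = r, lambda = config$lambda,
                                 C_b = config$C_b)),
          tailoras_error = function(e) NULL),
        `OSF-IPCW` = tryCatch(
          suppressWarnings(osf_ipcw(train, r = r, lambda = config$lambda)),
          tailoras_error = function(e) NULL))
      for (m in names(fits)) {
        if (is.null(fits[[m]])) {
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, scenario = config$scenario, n = config$n_train,
            T_gap = config$T_gap_train, r = r, replicate = i, seed = seed_i,
            oracle_tpr = NA_real_, oracle_tnr = NA_real_,
            oracle_value = NA_real_)
          next
        }
        orc <- oracle_performance(test, fits[[m]], config$landmarks,
                                  config$tau, r = r)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, scenario = config$scenario, n = config$n_train,
          T_gap = config$T_gap_train, r = r, replicate = i, seed = seed_i,
          oracle_tpr = mean(orc$tpr, na.rm = TRUE),
          oracle_tnr = mean(orc$tnr, na.rm = TRUE),
          oracle_value = attr(orc, "value"))
      }
    }
    if (verbose) message(sprintf("policy study: replicate %d/%d (seed %d)",
                                 i, config$n_rep, seed_i))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
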