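## Comparator estimators: IPCW (treats the first observed positive biopsy as
## a right-censored event time) and the current-status kernel estimator that
## ignores outcome-dependent dropout. Both are known to be biased under
## immediate dropout / interval censoring; they exist for the bias and
## policy-value comparisons.

## Surrogate right-censored representation: T* = first observed positive
## biopsy time (event), otherwise last observed biopsy time (censored).
surrogate_times <- function(cohort) {
  b <- cohort$biopsies
  event <- logical(cohort$n)
  tstar <- cohort$last_obs
  if (nrow(b) > 0) {
    pos <- b[b$result == 1L, , drop = FALSE]
    event[pos$id] <- TRUE
    tstar[pos$id] <- pos$time
  }
  data.frame(id = seq_len(cohort$n), tstar = tstar, event = event)
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Fits the Kaplan-Meier curve of the surrogate censoring time (last
#' observed biopsy when no positive is seen) and returns the left-continuous
#' survival function G(t-) = P(C* >= t) used for inverse weighting.
#'
#' @param cohort an `as_cohort`.
#' @return List with `G` (a function of time), `times`, `surv`, and `floor`,
#'   the smallest positive survival value (weights are capped at 1 / floor
#'   when the support is exhausted).
#' @export
km_censoring <- function(cohort) {
  st <- surrogate_times(cohort)
  fit <- survival::survfit(survival::Surv(st$tstar, !st$event) ~ 1)
  times <- fit$time
  surv <- fit$surv
  floor_val <- if (any(surv > 0)) min(surv[surv > 0]) else 1
  step <- stats::stepfun(times, c(1, surv), right = TRUE)  # left-continuous
  G <- function(t) pmax(step(t), floor_val)
  list(G = G, times = times, surv = surv, floor = floor_val)
}

#' IPCW estimates of TPR and TNR
#'
#' Treats the first observed positive biopsy time as a right-censored event
#' time T*, weights cases in (s, s + tau] by the inverse Kaplan-Meier
#' censoring survival at T*, and computes weighted decision proportions.
#' Under interval censoring T* is systematically later than the true
#' progression time, so these estimates are biased; they are the comparison
#' point for the kernel estimators.
#'
#' @inheritParams estimate_tnr
#' @return data.frame with columns s, tau, tpr, tnr.
#' @export
ipcw_tpr_tnr <- function(cohort, rule, s, tau) {
  st <- surrogate_times(cohort)
  km <- km_censoring(cohort)
  if (km$G(s + tau) <= km$floor && any(km$surv == 0)) {
    warning("censoring support exhausted before s + tau; IPCW weights capped")
  }
  d <- rule_decide(rule, landmark_covariates(cohort, s))
  case <- st$event & st$tstar > s & st$tstar <= s + tau
  ctrl <- st$tstar > s + tau
  wcase <- ifelse(case, 1 / km$G(st$tstar), 0)
  tpr <- if (sum(wcase) > 0) sum(wcase * (d == 1L)) / sum(wcase) else NA_real_
  tnr <- if (any(ctrl)) mean(d[ctrl] == -1L) else NA_real_
  data.frame(s = s, tau = tau, tpr = tpr, tnr = tnr)
}

## Current-status smoother F-hat_a(t) ~ P(d = a, T > t): share of
## kernel-weighted biopsy statuses at time t that are negative, within the
## decision stratum a. Uses every observed biopsy and ignores that positives
## after the first are never seen.
kr_cs_F <- function(cohort, d, a, t, h) {
  b <- cohort$biopsies
  k <- kernel_1d(b$time - t, h)
  da <- d[b$id] == a
  num <- sum(k * (b$result == 0L) * da) / cohort$n
  den <- sum(k) / cohort$n
  if (den <= 0) {
    no_support_error(sprintf("no biopsy with kernel mass near t = %g", t))
  }
  num / den
}

#' Current-status kernel estimates of TPR and TNR (dropout-naive)
#'
#' The panel current-status estimator: smooths biopsy statuses at s and
#' s + tau with a one-dimensional kernel and forms
#' TPR = \{F_1(s) - F_1(s+tau)\} / \{F(s) - F(s+tau)\},
#' TNR = F_-1(s+tau) / F(s+tau). Consistent when subjects keep being
#' observed after progression; biased under immediate dropout.
#'
#' @inheritParams estimate_tnr
#' @return data.frame with columns s, tau, tpr, tnr (clipped to [0, 1]).
#' @export
kr_cs_tpr_tnr <- function(cohort, rule, s, tau, h) {
  d <- rule_decide(rule, landmark_covariates(cohort, s))
  f1s <- kr_cs_F(cohort, d, 1L, s, h)
  f1t <- kr_cs_F(cohort, d, 1L, s + tau, h)
  fm1s <- kr_cs_F(cohort, d, -1L, s, h)
  fm1t <- kr_cs_F(cohort, d, -1L, s + tau, h)
  num_tpr <- f1s - f1t
  den_tpr <- (f1s + fm1s) - (f1t + fm1t)
  tpr <- if (abs(den_tpr) <= 0) NA_real_ else num_tpr / den_tpr
  den_tnr <- f1t + fm1t
  tnr <- if (den_tnr <= 0) NA_real_ else fm1t / den_tnr
  clip01 <- function(x) if (is.na(x)) x else min(max(x, 0), 1)
  data.frame(s = s, tau = tau, tpr = clip01(tpr), tnr = clip01(tnr))
}

#' @rdname kr_cs_tpr_tnr
#' @export
kr_cs_tpr <- function(cohort, rule, s, tau, h) {
  kr_cs_tpr_tnr(cohort, rule, s, tau, h)$tpr
}

## IPCW classification weights per landmark, mirroring the kernel weight
## systems: W1 ~ cases in (s, s+tau] inversely weighted by the censoring
## survival, W-1 ~ subjects still under observation past s + tau. Both are
## normalized to cohort mean 1. rho is estimated from the same weighted
## masses so the comparator's cost-benefit weight inherits its own scheme.
ipcw_weight_systems <- function(cohort, s, tau) {
  st <- surrogate_times(cohort)
  km <- km_censoring(cohort)
  case <- st$event & st$tstar > s & st$tstar <= s + tau
  ctrl <- st$tstar > s + tau
  w1 <- ifelse(case, 1 / km$G(st$tstar), 0)
  wm1 <- ifelse(ctrl, 1 / km$G(s + tau), 0)
  p1 <- mean(w1)
  p2 <- mean(wm1)
  if (p1 <= 0 || p2 <= 0) {
    no_support_error(sprintf("no IPCW mass at landmark s = %g", s))
  }
  list(w1 = w1 / p1, wm1 = wm1 / p2,
       rho = min(max(p1 / (p1 + p2), 1e-6), 1 - 1e-6))
}

#' IPCW-weighted surrogate-loss rule (comparator)
#'
#' Same surrogate-loss minimization as [osf_i()], with the kernel TPR / TNR
#' weights replaced by inverse-probability-of-censoring weights built from
#' the surrogate right-censored event time. Isolates the weighting scheme as
#' the point of comparison with the interval-censoring-aware learner.
#'
#' @inheritParams osf_i
#' @return An `osf_i`-classed object with `method = "OSF-IPCW"`.
#' @export
osf_ipcw <- function(cohort, landmarks = cohort$config$landmarks,
                     tau = cohort$config$tau,
                     tradeoff = NULL, r = NULL,
                     lambda = 0.01) {
  if (is.null(tradeoff)) {
    tradeoff <- if (!is.null(r)) tradeoff_cost_benefit(r) else tradeoff_fixed(1)
  }
  rows <- list()
  xi_used <- numeric(0)
  for (s in landmarks) {
    ws <- tryCatch(ipcw_weight_systems(cohort, s, tau),
                   noSupportError = function(e) NULL)
    if (is.null(ws)) next
    xi_s <- if (tradeoff$mode == "fixed_xi") {
      rep_len(tradeoff$xi, length(landmarks))[match(s, landmarks)]
    } else {
      xi_from_rho(ws$rho, tradeoff$r)
    }
    signed <- ws$w1 - xi_s * ws$wm1
    keep <- signed != 0
    if (!any(keep)) next
    Z <- landmark_covariates(cohort, s)[keep, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      id = which(keep), landmark = s,
      label = ifelse(signed[keep] > 0, 1L, -1L),
      weight = abs(signed[keep]), Z)
    xi_used <- c(xi_used, stats::setNames(xi_s, s))
  }
  if (!length(rows)) no_support_error("empty IPCW weighted sample")
  sample <- do.call(rbind, rows)
  rule <- fit_osf_i(sample, lambda)
  structure(list(rule = rule, xi = xi_used, sample_size = nrow(sample),
                 n = cohort$n, objective = attr(rule, "objective"),
                 landmarks = landmarks, tau = tau, lambda = lambda,
                 C_b = NA_real_, tradeoff = tradeoff, method = "OSF-IPCW",
                 call = match.call()),
            class = "osf_i")
}
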