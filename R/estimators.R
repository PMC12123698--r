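#' Kernel weights for the TNR estimator
#'
#' For each subject, the numerator sums K_h(N_k - t) over that subject's
#' observed negative biopsies. The weight is the numerator divided by its
#' sample mean over the eligible subset -- subjects whose last observed
#' biopsy time exceeds `t` -- so the eligible-subset mean of the returned
#' weights is exactly 1; ineligible subjects get weight 0.
#'
#' @param cohort an `as_cohort`.
#' @param t evaluation time (months); the TNR estimator calls this at
#'   t = s + tau.
#' @param h one-dimensional bandwidth.
#' @param warn_boundary warn when more than 20\% of the kernel mass at `t`
#'   falls outside the observed biopsy-time range.
#' @return Numeric vector of length n (per-subject weights).
#' @export
tnr_weights <- function(cohort, t, h, warn_boundary = TRUE) {
  stopifnot(t > 0, h > 0)
  b <- cohort$biopsies
  elig <- cohort$last_obs > t
  if (!any(elig)) {
    no_support_error(sprintf("no subject under observation beyond t = %g", t))
  }
  num <- numeric(cohort$n)
  neg <- b$result == 0
  if (any(neg)) {
    k <- kernel_1d(b$time[neg] - t, h)
    agg <- rowsum(k, group = b$id[neg], reorder = FALSE)
    num[as.integer(rownames(agg))] <- agg[, 1]
  }
  denom <- mean(num[elig])
  if (denom <= 0) {
    no_support_error(sprintf(
      "no negative biopsy within [%g, %g] among eligible subjects", t - h, t + h))
  }
  if (warn_boundary && nrow(b) > 0) {
    inside <- kernel_mass_inside(t, h, min(b$time), max(b$time))
    if (inside < 0.8) {
      warning(sprintf(
        "%.0f%% of kernel mass at t = %g lies outside the observed biopsy-time range",
        100 * (1 - inside), t))
    }
  }
  w <- num / denom
  w[!elig] <- 0
  w
}

#' Kernel weights for the TPR estimator (adjacent negative-positive pairs)
#'
#' Each subject contributes at most one adjacent observed negative-positive
#' biopsy pair (the baseline biopsy at time 0 counts as the initial
#' negative); the pair is smoothed by the two-dimensional kernel
#' K2((N_k - s - tau) / h, (N_(k) - s) / h) and the per-subject mass is
#' normalized by its mean over all n subjects, so the cohort-mean weight is
#' exactly 1.
#'
#' @param cohort an `as_cohort`.
#' @param s decision landmark (months).
#' @param tau months between landmark and the scheduled biopsy.
#' @param h_tilde two-dimensional bandwidth.
#' @return Numeric vector of length n.
#' @export
tpr_weights <- function(cohort, s, tau, h_tilde) {
  stopifnot(s > 0, tau > 0, h_tilde > 0)
  pr <- cohort$pairs
  np <- pr$res_prev == 0L & pr$res_curr == 1L
  num <- numeric(cohort$n)
  if (any(np)) {
    k <- kernel_2d(pr$t_curr[np] - s - tau, pr$t_prev[np] - s, h_tilde)
    agg <- rowsum(k, group = pr$id[np], reorder = FALSE)
    num[as.integer(rownames(agg))] <- agg[, 1]
  }
  denom <- mean(num)
  if (denom <= 0) {
    no_support_error(sprintf(
      "no negative-positive pair with kernel mass near (s, s + tau) = (%g, %g)",
      s, s + tau))
  }
  num / denom
}

#' Kernel estimator of the true negative rate of a rule
#'
#' TNR-hat(d; s, tau) = eligible-subset mean of 1\{d(Z_s) = -1\} W, with W the
#' [tnr_weights()] at t = s + tau. Always in [0, 1]; the constant rules
#' d = -1 / d = +1 give exactly 1 / 0.
#'
#' @param cohort an `as_cohort`.
#' @param rule a decision rule (see [linear_rule()]; also accepts +1/-1, a
#'   function of the covariate matrix, or a fitted [osf_i()] object).
#' @param s landmark time.
#' @param tau decision horizon (months).
#' @param h one-dimensional bandwidth.
#' @return Scalar estimate in [0, 1].
#' @export
estimate_tnr <- function(cohort, rule, s, tau, h) {
  w <- tnr_weights(cohort, s + tau, h)
  elig <- cohort$last_obs > s + tau
  d <- rule_decide(rule, landmark_covariates(cohort, s))
  mean((d[elig] == -1L) * w[elig])
}

#' Kernel estimator of the true positive rate of a rule
#'
#' TPR-hat(d; s, tau) = cohort mean of 1\{d(Z_s) = +1\} W, with W the
#' adjacent-pair weights of [tpr_weights()].
#'
#' @inheritParams estimate_tnr
#' @param h_tilde two-dimensional bandwidth.
#' @return Scalar estimate in [0, 1].
#' @export
estimate_tpr <- function(cohort, rule, s, tau, h_tilde) {
  w <- tpr_weights(cohort, s, tau, h_tilde)
  d <- rule_decide(rule, landmark_covariates(cohort, s))
  mean((d == 1L) * w)
}

#' Estimate the conditional progression probability rho(s; tau)
#'
#' rho(s; tau) = P(s < T <= s + tau | T > s) drives the cost-benefit weight
#' xi(s). Because each subject's progression time is bracketed by the last
#' negative and first positive observed biopsy regardless of dropout, rho is
#' a marginal functional of classic interval-censored data, and the default
#' estimator (`method = "pch"`) fits a piecewise-constant hazard by maximum
#' likelihood to those brackets (bins of width tau spanning the study
#' window) and returns 1 - S(s + tau) / S(s). This stays stable even when
#' biopsy gaps are much wider than tau, where pair-local smoothers
#' degenerate into extrapolation.
#'
#' Two kernel alternatives over adjacent negative-first biopsy pairs are
#' retained: conditional on such a pair at times (s, s + tau), the second
#' result is positive exactly when the event falls in (s, s + tau], so rho
#' is the regression of the second result on the pair times.
#' `method = "ll"` smooths that regression local-linearly in
#' (first time, gap), removing the first-order boundary bias at the
#' minimum-gap edge gap = T_gap; `method = "nw"` is the plain kernel-ratio
#' (Nadaraya-Watson) average, the smoothed count of negative-positive
#' against negative-negative pairs. Estimates are clipped to
#' [1e-6, 1 - 1e-6] so the cost-benefit weight xi stays finite.
#'
#' @details The local-linear smoother uses wider windows than the weight
#' systems (bandwidth 2 h_tilde in the gap coordinate, 6 h_tilde in the
#' first-time coordinate) and excludes baseline pairs (first biopsy paired
#' with the confirmatory biopsy at time 0), whose window always starts at 0.
#' With fewer than 8 pairs in the window it falls back to the weighted mean.
#'
#' @inheritParams estimate_tpr
#' @param method `"pch"` (piecewise-constant hazard, default), `"ll"`
#'   (local-linear) or `"nw"` (kernel ratio).
#' @param h_tilde bandwidth for the kernel methods; unused by `"pch"`.
#' @return Scalar in (0, 1).
#' @export
estimate_rho <- function(cohort, s, tau, h_tilde = NULL,
                         method = c("pch", "ll", "nw")) {
  stopifnot(s > 0, tau > 0)
  method <- match.arg(method)
  if (method == "pch") {
    S <- pch_survival(cohort, tau)
    denom <- S(s)
    if (denom <= 0) {
      no_support_error(sprintf("fitted survival vanishes at s = %g", s))
    }
    return(unname(min(max(1 - S(s + tau) / denom, 1e-6), 1 - 1e-6)))
  }
  stopifnot(h_tilde > 0)
  if (method == "nw") {
    pr <- cohort$pairs[cohort$pairs$res_prev == 0L, , drop = FALSE]
    k <- kernel_2d(pr$t_curr - s - tau, pr$t_prev - s, h_tilde)
    if (sum(k) <= 0) {
      no_support_error(sprintf(
        "no adjacent-pair kernel mass near (s, s + tau) = (%g, %g)", s, s + tau))
    }
    rho <- sum(k * pr$res_curr) / sum(k)
  } else {
    pr <- cohort$pairs[cohort$pairs$res_prev == 0L & cohort$pairs$t_prev > 0,
                       , drop = FALSE]
    g <- (pr$t_curr - pr$t_prev) - tau
    t1 <- pr$t_prev - s
    k <- kernel_1d(g, 2 * h_tilde) * kernel_1d(t1, 6 * h_tilde)
    pos <- k > 0
    if (!any(pos)) {
      no_support_error(sprintf(
        "no adjacent-pair kernel mass near (s, s + tau) = (%g, %g)", s, s + tau))
    }
    y <- as.numeric(pr$res_curr[pos])
    w <- k[pos]
    rho <- if (sum(pos) < 8L) {
      sum(w * y) / sum(w)
    } else {
      X <- cbind(1, g[pos], t1[pos])
      fit <- tryCatch(stats::lm.wfit(X, y, w), error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients)) {
        sum(w * y) / sum(w)         # degenerate design: fall back
      } else {
        fit$coefficients[1]
      }
    }
  }
  unname(min(max(rho, 1e-6), 1 - 1e-6))
}

#' Cost-benefit trade-off weight
#'
#' xi(s) = (1 - rho) / (rho r), where r is the number of unnecessary biopsies
#' one affords to catch one progression event within (s, s + tau].
#'
#' @param rho conditional progression probability in (0, 1).
#' @param r positive cost-benefit ratio.
#' @return Positive scalar.
#' @export
xi_from_rho <- function(rho, r) {
  stopifnot(r > 0)
  if (any(rho <= 0 | rho >= 1)) stop("'rho' must lie strictly inside (0, 1)")
  (1 - rho) / (rho * r)
}

#' Trade-off specifications
#'
#' `tradeoff_fixed(xi)` uses pre-specified trade-off weights (recycled over
#' landmarks); `tradeoff_cost_benefit(r)` derives xi(t_j) from the estimated
#' conditional progression probability via [xi_from_rho()].
#'
#' @param xi positive trade-off weight(s).
#' @param r positive cost-benefit ratio.
#' @return A `tradeoff` object.
#' @export
tradeoff_fixed <- function(xi) {
  stopifnot(all(xi > 0))
  structure(list(mode = "fixed_xi", xi = xi), class = "tradeoff")
}

#' @rdname tradeoff_fixed
#' @export
tradeoff_cost_benefit <- function(r) {
  stopifnot(length(r) == 1L, r > 0)
  structure(list(mode = "cost_benefit", r = r), class = "tradeoff")
}

## Resolve a tradeoff into per-landmark xi values; NA where rho has no
## kernel support.
resolve_xi <- function(cohort, landmarks, tradeoff, tau, bw) {
  stopifnot(inherits(tradeoff, "tradeoff"))
  if (tradeoff$mode == "fixed_xi") {
    return(rep_len(tradeoff$xi, length(landmarks)))
  }
  vapply(landmarks, function(s) {
    tryCatch(xi_from_rho(estimate_rho(cohort, s, tau, bw$h_tilde), tradeoff$r),
             noSupportError = function(e) NA_real_)
  }, numeric(1))
}

#' Weighted-benefits value of a rule
#'
#' Phi-hat(d) = J^{-1} sum_j [TPR-hat(t_j) + xi(t_j) TNR-hat(t_j)] over the
#' decision landmarks. Landmarks without kernel support are dropped with a
#' warning (J reduced); if none is supported an error of class
#' `noSupportError` is raised.
#'
#' @param cohort an `as_cohort`.
#' @param rule a decision rule.
#' @param landmarks decision times t_j.
#' @param tradeoff a [tradeoff_fixed()] or [tradeoff_cost_benefit()].
#' @param tau decision horizon.
#' @param bw bandwidths from [bandwidths()].
#' @return Scalar estimated value.
#' @export
estimate_value <- function(cohort, rule, landmarks = cohort$config$landmarks,
                           tradeoff = tradeoff_fixed(1),
                           tau = cohort$config$tau,
                           bw = bandwidths(48, cohort$n)) {
  xi <- resolve_xi(cohort, landmarks, tradeoff, tau, bw)
  vals <- rep(NA_real_, length(landmarks))
  for (j in seq_along(landmarks)) {
    s <- landmarks[j]
    if (is.na(xi[j])) next
    vals[j] <- tryCatch(
      estimate_tpr(cohort, rule, s, tau, bw$h_tilde) +
        xi[j] * estimate_tnr(cohort, rule, s, tau, bw$h),
      noSupportError = function(e) NA_real_)
  }
  keep <- !is.na(vals)
  if (!any(keep)) {
    no_support_error("no landmark with kernel support; cannot estimate the value")
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d unsupported landmark(s): %s",
                    sum(!keep), paste(landmarks[!keep], collapse = ", ")))
  }
  mean(vals[keep])
}

#' Per-landmark kernel performance estimates of a rule
#'
#' Convenience wrapper returning a data frame with one row per landmark:
#' TPR-hat, TNR-hat, rho-hat, xi and the effective kernel masses.
#'
#' @inheritParams estimate_value
#' @return data.frame with columns s, tau, tpr, tnr, rho, xi, n_eff_pos,
#'   n_eff_neg.
#' @export
estimate_performance <- function(cohort, rule,
                                 landmarks = cohort$config$landmarks,
                                 tradeoff = tradeoff_fixed(1),
                                 tau = cohort$config$tau,
                                 bw = bandwidths(48, cohort$n)) {
  xi <- resolve_xi(cohort, landmarks, tradeoff, tau, bw)
  out <- lapply(seq_along(landmarks), function(j) {
    s <- landmarks[j]
    row <- data.frame(s = s, tau = tau, tpr = NA_real_, tnr = NA_real_,
                      rho = NA_real_, xi = xi[j],
                      n_eff_pos = NA_real_, n_eff_neg = NA_real_)
    tryCatch({
      wp <- tpr_weights(cohort, s, tau, bw$h_tilde)
      wn <- tnr_weights(cohort, s + tau, bw$h)
      d <- rule_decide(rule, landmark_covariates(cohort, s))
      elig <- cohort$last_obs > s + tau
      row$tpr <- mean((d == 1L) * wp)
      row$tnr <- mean((d[elig] == -1L) * wn[elig])
      row$rho <- tryCatch(estimate_rho(cohort, s, tau, bw$h_tilde),
                          noSupportError = function(e) NA_real_)
      row$n_eff_pos <- sum(wp > 0)
      row$n_eff_neg <- sum(wn > 0)
      row
    }, noSupportError = function(e) row)
  })
  do.call(rbind, out)
}
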