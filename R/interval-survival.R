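## Marginal survival of the progression time from the interval-censored
## reductions (last negative biopsy, first positive biopsy]: maximum
## likelihood under a piecewise-constant hazard. Used by estimate_rho's
## default method; the fit is cached on the cohort (keyed by the breaks).

interval_brackets <- function(cohort) {
  b <- cohort$biopsies
  L <- numeric(cohort$n)
  R <- rep(Inf, cohort$n)
  neg <- b[b$result == 0L, , drop = FALSE]
  pos <- b[b$result == 1L, , drop = FALSE]
  if (nrow(neg)) {
    mx <- tapply(neg$time, neg$id, max)
    L[as.integer(names(mx))] <- mx
  }
  if (nrow(pos)) {
    mn <- tapply(pos$time, pos$id, min)
    R[as.integer(names(mn))] <- mn
  }
  data.frame(id = seq_len(cohort$n), L = L, R = R)
}

## Bin-overlap matrix: row i gives the time subject value t_i spends in each
## hazard bin; exposure beyond the last break accrues to the last bin.
pch_exposure <- function(t, breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  m <- sweep(outer(t, hi, pmin), 2, lo)
  m[m < 0] <- 0
  m[, ncol(m)] <- m[, ncol(m)] + pmax(0, t - breaks[length(breaks)])
  m
}

pch_survival <- function(cohort, tau, breaks = NULL) {
  cfg <- cohort$config
  if (is.null(breaks)) {
    breaks <- seq(cfg$entry_offset, cfg$horizon + tau, by = tau)
  }
  key <- paste0("pch_", paste(signif(breaks, 10), collapse = "_"))
  if (!is.null(cohort$cache) && !is.null(cohort$cache[[key]])) {
    return(cohort$cache[[key]])
  }
  br <- interval_brackets(cohort)
  keep <- br$L > 0 | is.finite(br$R)
  if (!any(keep)) {
    no_support_error("no subject carries an informative progression bracket")
  }
  L <- br$L[keep]
  R <- br$R[keep]
  DL <- pch_exposure(L, breaks)
  fin <- is.finite(R)
  DR <- pch_exposure(ifelse(fin, R, 0), breaks)
  nll <- function(theta) {
    lam <- exp(theta)
    SL <- exp(-drop(DL %*% lam))
    SR <- ifelse(fin, exp(-drop(DR %*% lam)), 0)
    -sum(log(pmax(SL - SR, 1e-300)))
  }
  opt <- stats::optim(rep(log(0.02), length(breaks) - 1L), nll,
                      method = "BFGS", control = list(maxit = 1000))
  lam <- exp(opt$par)
  S <- function(t) exp(-drop(pch_exposure(t, breaks) %*% lam))
  if (!is.null(cohort$cache)) cohort$cache[[key]] <- S
  S
}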