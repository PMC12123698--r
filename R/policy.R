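#' Build the weighted classification sample for surrogate-loss fitting
#'
#' Stacks one row per (subject, landmark) with a nonzero signed weight
#' W_1(t_j) - xi(t_j) W_-1(t_j + tau): the label is the sign (+1 = the
#' kernel evidence favours a biopsy), the weight its absolute value. The
#' eligibility-normalized TNR weights are rescaled to a full-cohort mean so
#' both terms share the same empirical measure. Landmarks where either
#' weight system (or rho-hat, under a cost-benefit trade-off) has no kernel
#' support are dropped with a warning.
#'
#' @inheritParams estimate_value
#' @return data.frame of class `weighted_sample` with columns id, landmark,
#'   label, weight, z1..zp; attributes `J` (landmarks used), `n`, `xi`.
#' @export
build_weighted_sample <- function(cohort, landmarks = cohort$config$landmarks,
                                  tradeoff = tradeoff_fixed(1),
                                  tau = cohort$config$tau,
                                  bw = bandwidths(48, cohort$n)) {
  xi <- resolve_xi(cohort, landmarks, tradeoff, tau, bw)
  rows <- list()
  used <- logical(length(landmarks))
  for (j in seq_along(landmarks)) {
    s <- landmarks[j]
    if (is.na(xi[j])) next
    w1 <- tryCatch(tpr_weights(cohort, s, tau, bw$h_tilde),
                   noSupportError = function(e) NULL)
    wm1 <- tryCatch(tnr_weights(cohort, s + tau, bw$h),
                    noSupportError = function(e) NULL)
    if (is.null(w1) || is.null(wm1)) next
    elig <- cohort$last_obs > s + tau
    wm1 <- wm1 * cohort$n / sum(elig)   # mean 1 over the full cohort
    signed <- w1 - xi[j] * wm1
    keep <- signed != 0
    if (!any(keep)) next
    Z <- landmark_covariates(cohort, s)[keep, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      id = which(keep), landmark = s,
      label = ifelse(signed[keep] > 0, 1L, -1L),
      weight = abs(signed[keep]), Z)
    used[j] <- TRUE
  }
  if (!length(rows)) {
    no_support_error("empty weighted sample: no landmark with kernel support")
  }
  if (any(!used)) {
    warning(sprintf("dropping %d unsupported landmark(s): %s",
                    sum(!used), paste(landmarks[!used], collapse = ", ")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, J = sum(used), n = cohort$n,
            xi = stats::setNames(xi[used], landmarks[used]),
            class = c("weighted_sample", "data.frame"))
}

## Penalized surrogate objective: mean over rows of
## w * log(1 + exp(-y f)) + lambda * ||beta||^2, intercept unpenalized.
## `theta` = c(intercept, beta); X carries the intercept column.
osf_objective <- function(theta, X, y, w, lambda, n_div = length(y)) {
  f <- drop(X %*% theta)
  sum(w * log1p(exp(-y * f))) / n_div + lambda * sum(theta[-1]^2)
}

osf_gradient <- function(theta, X, y, w, lambda, n_div = length(y)) {
  f <- drop(X %*% theta)
  p <- stats::plogis(-y * f)          # sigma(-y f)
  g <- crossprod(X, -y * w * p) / n_div
  g[-1] <- g[-1] + 2 * lambda * theta[-1]
  drop(g)
}

#' Fit the surrogate-loss linear rule on a weighted sample
#'
#' Minimizes the convex penalized objective
#' mean_rows\{w * log(1 + exp(-y f(Z)))\} + lambda ||beta||^2 with a linear
#' f and unpenalized intercept, by damped Newton iterations (step-halving
#' line search). Weights are first scaled to mean 1 within each landmark so
#' the ridge penalty has a stable interpretation across sample sizes and
#' bandwidths.
#'
#' @param sample a [build_weighted_sample()] result (or any data.frame with
#'   columns label, weight, z1..zp and optionally landmark).
#' @param lambda nonnegative ridge penalty.
#' @param max_iter,tol Newton iteration controls.
#' @return A [linear_rule()] with the fitted coefficients; attributes
#'   `objective` (at the optimum), `iterations`, `converged`.
#' @export
fit_osf_i <- function(sample, lambda, max_iter = 100L, tol = 1e-10) {
  stopifnot(nrow(sample) > 0, lambda >= 0)
  zcols <- grep("^z[0-9]+$", names(sample), value = TRUE)
  if (!length(zcols)) stop("sample has no covariate columns z1..zp")
  w <- sample$weight
  if (!is.null(sample$landmark)) {
    w <- w / stats::ave(w, sample$landmark, FUN = mean)
  } else {
    w <- w / mean(w)
  }
  y <- as.numeric(sample$label)
  X <- cbind(`(Intercept)` = 1, as.matrix(sample[, zcols, drop = FALSE]))
  d <- ncol(X)
  theta <- numeric(d)
  obj <- osf_objective(theta, X, y, w, lambda)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f <- drop(X %*% theta)
    pq <- stats::plogis(y * f) * stats::plogis(-y * f)   # sigma'(yf)
    g <- osf_gradient(theta, X, y, w, lambda)
    H <- crossprod(X, X * (w * pq)) / nrow(X)
    diag(H)[-1] <- diag(H)[-1] + 2 * lambda
    diag(H) <- diag(H) + 1e-12                            # numerical floor
    step <- tryCatch(solve(H, g), error = function(e) g)
    sz <- 1
    repeat {
      cand <- theta - sz * step
      cobj <- osf_objective(cand, X, y, w, lambda)
      if (cobj <= obj + 1e-14 || sz < 1e-8) break
      sz <- sz / 2
    }
    moved <- obj - cobj
    theta <- cand
    obj <- cobj
    if (max(abs(g)) < tol || moved < 1e-14) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    optimization_error("Newton iterations did not converge",
                       diagnostics = list(iterations = it,
                                          grad = osf_gradient(theta, X, y, w, lambda),
                                          objective = obj))
  }
  rule <- linear_rule(stats::setNames(theta[-1], zcols), unname(theta[1]),
                      lambda = lambda)
  attr(rule, "objective") <- obj
  attr(rule, "iterations") <- it
  attr(rule, "converged") <- converged
  rule
}

#' Fit an optimally tailored surveillance rule (OSF-I)
#'
#' The main fitting function. Builds kernel TPR / TNR classification weights
#' at each decision landmark, resolves the trade-off weight xi (fixed, or
#' cost-benefit via the estimated conditional progression probability), and
#' minimizes the penalized logistic surrogate of the weighted-benefits value
#' to obtain a stabilized linear rule d(Z) = sgn(f(Z)).
#'
#' @param cohort an `as_cohort` (from [simulate_cohort()] or [read_cohort()]).
#' @param landmarks decision landmark times t_j (months).
#' @param tau months between a decision and the biopsy it schedules.
#' @param tradeoff a [tradeoff_fixed()] or [tradeoff_cost_benefit()]
#'   specification; `r` is shorthand for `tradeoff_cost_benefit(r)`.
#' @param r cost-benefit ratio shorthand (ignored when `tradeoff` is given).
#' @param lambda ridge penalty on the linear coefficients.
#' @param C_b bandwidth constant; h = C_b n^{-1/5}, h_tilde = C_b n^{-1/6}.
#' @return Object of class `osf_i` with components `rule` (a
#'   [linear_rule()]), `xi`, `sample_size`, `objective`, `landmarks`, `tau`,
#'   `lambda`, `C_b`, `call`.
#' @seealso [cv_osf_i()] for tuning (lambda, C_b) by cross-validation;
#'   [predict.osf_i()]; [estimate_performance()].
#' @export
#' @examples
#' coh <- simulate_cohort(200, scenario_config(1), seed = 1)
#' fit <- osf_i(coh, r = 4, lambda = 0.01, C_b = 48)
#' fit
#' predict(fit, landmark_covariates(coh, 48))[1:5]
osf_i <- function(cohort, landmarks = cohort$config$landmarks,
                  tau = cohort$config$tau,
                  tradeoff = NULL, r = NULL,
                  lambda = 0.01, C_b = 48) {
  if (is.null(tradeoff)) {
    tradeoff <- if (!is.null(r)) tradeoff_cost_benefit(r) else tradeoff_fixed(1)
  }
  bw <- bandwidths(C_b, cohort$n)
  sample <- build_weighted_sample(cohort, landmarks, tradeoff, tau, bw)
  rule <- fit_osf_i(sample, lambda)
  rule$C_b <- C_b
  structure(list(rule = rule, xi = attr(sample, "xi"),
                 sample_size = nrow(sample), n = cohort$n,
                 objective = attr(rule, "objective"),
                 landmarks = landmarks, tau = tau, lambda = lambda, C_b = C_b,
                 tradeoff = tradeoff, method = "OSF-I",
                 call = match.call()),
            class = "osf_i")
}

#' @export
print.osf_i <- function(x, ...) {
  cat(x$method, "tailored surveillance rule\n")
  cat("  d(Z) = sgn(", format(x$rule$intercept, digits = 4), "+ coef'Z ), coefficients:\n")
  print(round(x$rule$coefficients, 4))
  cat("  landmarks:", paste(x$landmarks, collapse = ", "),
      "| tau:", x$tau, "\n")
  cat("  lambda:", x$lambda, "| C_b:", x$C_b,
      "| weighted rows:", x$sample_size, "of", x$n, "subjects\n")
  invisible(x)
}

#' @export
summary.osf_i <- function(object, ...) {
  cat("Call: ")
  print(object$call)
  print(object)
  cat("  trade-off xi per landmark:\n")
  print(round(object$xi, 4))
  cat("  penalized surrogate objective at optimum:",
      format(object$objective, digits = 6), "\n")
  invisible(object)
}

#' @export
coef.osf_i <- function(object, ...) {
  c(`(Intercept)` = object$rule$intercept, object$rule$coefficients)
}

#' Predict biopsy decisions from a fitted rule
#'
#' @param object a fitted [osf_i()] rule.
#' @param newdata matrix or data.frame of current covariates (columns
#'   z1..zp, or in the coefficient order).
#' @param type `"class"` for decisions in \{+1, -1\} (ties to +1),
#'   `"link"` for the linear score f(Z).
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.osf_i <- function(object, newdata, type = c("class", "link"), ...) {
  type <- match.arg(type)
  Z <- as.matrix(newdata)
  nm <- names(object$rule$coefficients)
  if (!is.null(colnames(Z)) && all(nm %in% colnames(Z))) {
    Z <- Z[, nm, drop = FALSE]
  }
  f <- object$rule$intercept + drop(Z %*% object$rule$coefficients)
  if (type == "link") f else ifelse(f >= 0, 1L, -1L)
}

#' Cross-validated OSF-I fit
#'
#' Subject-level K-fold cross-validation over a grid of (lambda, C_b): for
#' each pair the rule is fitted on the training folds and scored by the
#' kernel-estimated weighted-benefits value on the held-out fold (weights
#' recomputed on held-out data with held-out-size bandwidths; xi resolved on
#' the training folds). The pair with the highest mean held-out value is
#' refitted on the full cohort.
#'
#' @inheritParams osf_i
#' @param lambda_grid,Cb_grid candidate values.
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold split.
#' @return An `osf_i` object with an extra `cv_table` component
#'   (lambda, C_b, mean held-out value, folds used).
#' @export
cv_osf_i <- function(cohort, lambda_grid, Cb_grid,
                     landmarks = cohort$config$landmarks,
                     tau = cohort$config$tau,
                     tradeoff = tradeoff_fixed(1),
                     folds = 5L, seed = 1L) {
  stopifnot(folds >= 2L, length(lambda_grid) >= 1L, length(Cb_grid) >= 1L)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), cohort$n))
  grid <- expand.grid(lambda = sort(lambda_grid), C_b = sort(Cb_grid))
  grid$value <- NA_real_
  grid$folds_used <- 0L
  for (g in seq_len(nrow(grid))) {
    vals <- rep(NA_real_, folds)
    for (f in seq_len(folds)) {
      train <- subset_cohort(cohort, which(fold_id != f))
      test <- subset_cohort(cohort, which(fold_id == f))
      vals[f] <- tryCatch({
        bw_tr <- bandwidths(grid$C_b[g], train$n)
        xi_tr <- resolve_xi(train, landmarks, tradeoff, tau, bw_tr)
        fit <- fit_osf_i(
          build_weighted_sample(train, landmarks, tradeoff, tau, bw_tr),
          grid$lambda[g])
        ok <- !is.na(xi_tr)
        if (!any(ok)) no_support_error("no landmark resolvable on training folds")
        estimate_value(test, fit, landmarks[ok], tradeoff_fixed(xi_tr[ok]),
                       tau, bandwidths(grid$C_b[g], test$n))
      }, noSupportError = function(e) NA_real_,
         optimizationError = function(e) NA_real_)
    }
    if (all(is.na(vals))) {
      warning(sprintf("all folds unsupported for lambda = %g, C_b = %g",
                      grid$lambda[g], grid$C_b[g]))
    }
    grid$value[g] <- mean(vals, na.rm = TRUE)
    grid$folds_used[g] <- sum(!is.na(vals))
  }
  if (all(is.na(grid$value))) {
    stop("cross-validation failed on every configuration")
  }
  best <- which.max(grid$value)
  fit <- osf_i(cohort, landmarks, tau, tradeoff = tradeoff,
               lambda = grid$lambda[best], C_b = grid$C_b[best])
  fit$cv_table <- grid
  fit$call <- match.call()
  fit
}
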