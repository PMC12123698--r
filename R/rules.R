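#' Linear decision rule
#'
#' A stabilized surveillance rule d(Z) = sgn(intercept + coef' Z) applied with
#' the current covariates at each decision landmark; ties (f = 0) map to +1,
#' the conservative biopsy decision.
#'
#' @param coefficients numeric vector (one per covariate, names optional).
#' @param intercept scalar intercept.
#' @param lambda,C_b optional tuning values recorded for provenance.
#' @return Object of class `linear_rule`.
#' @export
linear_rule <- function(coefficients, intercept = 0, lambda = NA_real_,
                        C_b = NA_real_) {
  stopifnot(is.numeric(coefficients), is.numeric(intercept),
            length(intercept) == 1L)
  structure(list(coefficients = coefficients, intercept = intercept,
                 lambda = lambda, C_b = C_b),
            class = "linear_rule")
}

#' @export
print.linear_rule <- function(x, ...) {
  cat("Linear surveillance rule: d(Z) = sgn(",
      format(x$intercept, digits = 4), "+ coef'Z )\n")
  print(x$coefficients)
  invisible(x)
}

## Evaluate a decision rule on an n x p covariate matrix -> vector in {+1,-1}.
## Accepts: a linear_rule, an osf_i fit, a function(Z) -> {+1,-1}, or the
## constants +1 / -1.
rule_decide <- function(rule, Z) {
  if (inherits(rule, "osf_i")) rule <- rule$rule
  if (inherits(rule, "linear_rule")) {
    f <- rule$intercept + drop(Z %*% rule$coefficients)
    return(ifelse(f >= 0, 1L, -1L))
  }
  if (is.function(rule)) {
    d <- rule(Z)
    if (!all(d %in% c(-1, 1))) stop("rule function must return values in {+1, -1}")
    return(as.integer(d))
  }
  if (is.numeric(rule) && length(rule) == 1L && rule %in% c(-1, 1)) {
    return(rep(as.integer(rule), nrow(Z)))
  }
  stop("unsupported decision rule; supply a linear_rule, osf_i fit, function, or +1/-1")
}
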