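#' Epanechnikov kernel, scaled by bandwidth
#'
#' Univariate kernel K_h(x) = K(x / h) / h with K(u) = 0.75 (1 - u^2) on
#' [-1, 1]. Second-order, compactly supported, which matches the bandwidth
#' rates h = C_b n^{-1/5} and h_tilde = C_b n^{-1/6} used throughout.
#'
#' @param x numeric vector of evaluation points (months).
#' @param h positive bandwidth (months).
#' @return Nonnegative kernel values; zero outside [-h, h].
#' @seealso [kernel_2d()], [bandwidths()]
#' @export
#' @examples
#' kernel_1d(0, 2)  # 0.375
kernel_1d <- function(x, h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    stop("'h' must be a single positive bandwidth")
  }
  u <- x / h
  ifelse(abs(u) <= 1, 0.75 * (1 - u^2) / h, 0)
}

#' Product Epanechnikov kernel in two dimensions
#'
#' K2_h(x1, x2) = K(x1 / h) K(x2 / h) / h^2, used to smooth over the two
#' biopsy times of an adjacent negative-positive pair.
#'
#' @param x1,x2 numeric vectors of evaluation points (months).
#' @param h positive bandwidth (months), common to both coordinates.
#' @return Nonnegative kernel values; zero when either coordinate is outside
#'   [-h, h].
#' @export
#' @examples
#' kernel_2d(0, 0, 2)  # 0.140625
kernel_2d <- function(x1, x2, h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    stop("'h' must be a single positive bandwidth")
  }
  u <- x1 / h
  v <- x2 / h
  ifelse(abs(u) <= 1 & abs(v) <= 1,
         0.75 * (1 - u^2) * 0.75 * (1 - v^2) / h^2, 0)
}

#' Bandwidths from the constant C_b and sample size
#'
#' Returns h = C_b n^{-1/5} for the one-dimensional (TNR) smoother and
#' h_tilde = C_b n^{-1/6} for the two-dimensional (pair) smoother. These
#' rates minimise the generalization-error bound for a second-order kernel;
#' C_b itself is a tuning constant, typically chosen by cross-validation
#' (see [cv_osf_i()]).
#'
#' @param C_b positive constant (months scale).
#' @param n sample size (number of subjects).
#' @return List with components `h`, `h_tilde`, `C_b`, `n`.
#' @export
bandwidths <- function(C_b, n) {
  stopifnot(is.numeric(C_b), length(C_b) == 1L, C_b > 0,
            is.numeric(n), length(n) == 1L, n >= 1)
  list(C_b = C_b, n = n, h = C_b * n^(-1 / 5), h_tilde = C_b * n^(-1 / 6))
}

## CDF of the Epanechnikov kernel on [-1, 1]; used to assess how much kernel
## mass falls outside the observed biopsy-time range (boundary diagnostics).
epa_cdf <- function(u) {
  u <- pmin(1, pmax(-1, u))
  0.25 * (2 + 3 * u - u^3)
}

## Fraction of K_h(. - t) mass inside [lo, hi].
kernel_mass_inside <- function(t, h, lo, hi) {
  epa_cdf((hi - t) / h) - epa_cdf((lo - t) / h)
}
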