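#' Pseudotime polynomial basis matrix
#'
#' Discretizes the pseudotime axis `[0, 1]` into `K + 1` equidistant stages
#' (stage 0 is the control anchor at t = 0, stage `K` is t = 1) and expands
#' each stage value into its first `D` powers. The resulting basis matrix
#' `T` has entry `(k, d) = (k/K)^d` for `k = 0..K`, `d = 1..D`; multiplying
#' it by a coefficient matrix evaluates every feature polynomial at every
#' stage. Because the constant term is omitted, every trajectory passes
#' through zero at stage 0: the model anchors all features at their
#' normative (control) value at the start of the progression.
#'
#' @param K Positive integer, number of non-zero stages. The model has
#'   `K + 1` stages in total.
#' @param D Positive integer, maximal polynomial degree.
#'
#' @return An object of class `ppsi_basis`: a list with elements `K`, `D`
#'   and `T`, the `(K+1) x D` basis matrix.
#'
#' @examples
#' b <- build_basis(K = 2, D = 2)
#' b$T  # rows (0,0), (0.5,0.25), (1,1)
#' @export
build_basis <- function(K, D) {
  if (!is_count(K)) stop("`K` must be a positive integer", call. = FALSE)
  if (!is_count(D)) stop("`D` must be a positive integer", call. = FALSE)
  K <- as.integer(K)
  D <- as.integer(D)
  t_k <- (0:K) / K
  T <- outer(t_k, seq_len(D), `^`)
  structure(list(K = K, D = D, T = T), class = "ppsi_basis")
}

#' Precomputed Gaussian likelihood constants
#'
#' The stage/subtype likelihood uses a normal density with a single fixed
#' standard deviation `sigma` shared by every stage-cluster. Fixing sigma
#' allows the two density constants to be computed once: the coefficient
#' `alpha = 1 / (sigma * sqrt(2 * pi))` and the exponent denominator
#' `beta = 2 * sigma^2`. The memoized log-density is then
#' `log(alpha) - (x - mu)^2 / beta`.
#'
#' @param sigma Positive real, the fixed cluster standard deviation.
#' @return An object of class `ppsi_gauss` with fields `sigma`, `alpha`,
#'   `beta` and `log_alpha`.
#' @export
gaussian_constants <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a positive finite number", call. = FALSE)
  }
  alpha <- 1 / (sigma * sqrt(2 * pi))
  beta <- 2 * sigma^2
  structure(
    list(sigma = sigma, alpha = alpha, beta = beta, log_alpha = log(alpha)),
    class = "ppsi_gauss"
  )
}

#' Fixed-sigma memoized Gaussian log-density
#'
#' Evaluates `log(alpha) - (x - mu)^2 / beta`, the log of the normal
#' density with mean `mu` and the fixed standard deviation carried by
#' `constants`. Vectorized over `mu` and `x`.
#'
#' @param mu Numeric vector of means.
#' @param x Numeric vector of observed values.
#' @param constants A [gaussian_constants()] object.
#' @return Numeric vector of log-densities.
#' @export
log_pdf <- function(mu, x, constants) {
  stopifnot(inherits(constants, "ppsi_gauss"))
  constants$log_alpha - (x - mu)^2 / constants$beta
}

# positive scalar integer check
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
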