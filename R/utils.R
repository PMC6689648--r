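# Internal numeric helpers shared across the inference code.

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector (may contain -Inf).
#' @return scalar log-sum-exp.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Multivariate log-gamma function log Gamma_D(a)
#' @keywords internal
lmvgamma <- function(a, D) {
  D * (D - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(D)) / 2))
}

#' Log-determinant of a symmetric positive-definite matrix via Cholesky
#' @keywords internal
logdet_spd <- function(S) {
  2 * sum(log(diag(chol(S))))
}

# digamma with the argument floored away from 0 (guards exp(E[log phi])
# against -Inf from numerically zero pseudo-counts)
digamma_safe <- function(x, floor = 1e-10) digamma(pmax(x, floor))

#' Deterministic child seed derived from a master seed
#'
#' All stochastic stages consume named sub-seeds so that one master seed
#' reproduces an entire experiment. Values stay below 2^31 - 1.
#' @keywords internal
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
}

# stack per-item D-vectors from FUN into an n x D matrix (vapply collapses
# to a plain vector when D = 1, so plain t() is wrong there)
stack_rows <- function(items, FUN, D) {
  m <- vapply(items, FUN, numeric(D))
  if (D == 1) matrix(m, ncol = 1) else t(m)
}
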