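# Truncated stick-breaking (GEM) weights and their degenerate variational
# update. The top-level HDP weights (beta over non-terminals, gamma over
# terminals, omega over HMM states) get point-mass variational factors
# truncated at K components; they are re-optimized by numerical ascent on
# the ELBO terms that involve them, with updates accepted only when they
# improve the objective (preserving coordinate-ascent monotonicity).

#' Stick weights from stick-breaking fractions
#' @param v vector of K - 1 fractions in (0, 1).
#' @return length-K probability vector (last stick takes the remainder).
#' @export
stick_break <- function(v) {
  rem <- cumprod(1 - v)
  c(v, 1) * c(1, rem)
}

#' Sample truncated GEM stick weights
#' @param K truncation level.
#' @param alpha concentration of the Beta(1, alpha) stick fractions.
#' @return length-K probability vector.
#' @export
sample_gem <- function(K, alpha = 1) {
  if (K == 1) return(1)
  stick_break(stats::rbeta(K - 1, 1, alpha))
}

#' Log density of truncated GEM weights
#'
#' Density of the first K - 1 coordinates of the stick-breaking construction
#' with Beta(1, alpha) fractions (the K-th weight is the remainder),
#' including the fraction-to-weight Jacobian.
#'
#' @param beta length-K probability vector with positive entries.
#' @param alpha GEM concentration.
#' @return scalar log density (`-Inf` for degenerate inputs).
#' @export
gem_log_density <- function(beta, alpha = 1) {
  K <- length(beta)
  if (K == 1) return(0)
  if (any(beta <= 0) || abs(sum(beta) - 1) > 1e-8) return(-Inf)
  rem <- 1 - cumsum(c(0, beta[seq_len(K - 2)])) # remainder before stick i
  v <- beta[seq_len(K - 1)] / rem
  if (any(v >= 1)) return(-Inf)
  sum(log(alpha) + (alpha - 1) * log1p(-v) - log(rem))
}

#' ELBO contribution of one Dirichlet factor's prior term
#'
#' `E_q[log Dir(phi; a)]` where q is Dirichlet with parameters `d`. The base
#' counts `a` depend on the stick weights, so this is the piece the
#' degenerate stick update climbs.
#' @keywords internal
elbo_dir_prior_term <- function(d, a) {
  el <- digamma(d) - digamma(sum(d))
  lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * el)
}

#' Negative KL divergence of a Dirichlet factor from its prior
#' @param d variational Dirichlet parameters.
#' @param a prior (base-count) Dirichlet parameters.
#' @return `E_q[log p] - E_q[log q]`.
#' @export
dirichlet_neg_kl <- function(d, a) {
  elbo_dir_prior_term(d, a) - elbo_dir_prior_term(d, d)
}

#' Re-optimize degenerate stick weights by accepted-ascent
#'
#' Maximizes `objective(beta)` over the open simplex via a softmax
#' parametrization and BFGS; the result is kept only if it improves the
#' objective, so callers inside a coordinate-ascent sweep never lose ELBO.
#'
#' @param beta0 current stick weights (starting point).
#' @param objective function of a length-K probability vector.
#' @param maxit BFGS iteration budget.
#' @return list with `beta` and `value = objective(beta)`.
#' @export
optimize_sticks <- function(beta0, objective, maxit = 60) {
  f0 <- objective(beta0)
  K <- length(beta0)
  if (K == 1) return(list(beta = beta0, value = f0))
  z0 <- log(pmax(beta0, 1e-8))
  negf <- function(z) {
    b <- exp(z - max(z)); b <- b / sum(b)
    v <- objective(b)
    if (!is.finite(v)) 1e12 else -v
  }
  opt <- tryCatch(
    stats::optim(z0, negf, method = "BFGS", control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(opt)) return(list(beta = beta0, value = f0))
  b <- exp(opt$par - max(opt$par)); b <- b / sum(b)
  v <- objective(b)
  if (is.finite(v) && v > f0) list(beta = b, value = v)
  else list(beta = beta0, value = f0)
}
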