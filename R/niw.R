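# Normal-inverse-Wishart (NIW) conjugate machinery for Gaussian emissions.
#
# Parametrization: (mu, Sigma) ~ NIW(m, kappa, Psi, nu) means
#   Sigma ~ InvWishart(Psi, nu),  mu | Sigma ~ N(m, Sigma / kappa),
# with nu > D - 1. Default prior: m0 = sample mean of all feature
# vectors, Psi0 = identity, nu0 = D - 1 + 0.001, kappa0 = nu0.

#' Construct NIW parameters
#' @param m mean vector (length D).
#' @param kappa scalar precision multiplier (> 0).
#' @param Psi D x D positive-definite scale matrix.
#' @param nu degrees of freedom (> D - 1).
#' @return a `niw` parameter list.
#' @export
niw_params <- function(m, kappa, Psi, nu) {
  D <- length(m)
  Psi <- as.matrix(Psi)
  if (!all(dim(Psi) == D)) stop("`Psi` must be D x D")
  if (kappa <= 0 || nu <= D - 1) stop("need kappa > 0 and nu > D - 1")
  list(m = as.numeric(m), kappa = kappa, Psi = Psi, nu = nu, D = D)
}

#' The pipeline's default NIW prior for a feature matrix
#' @param X n x D matrix of feature vectors (rows are observations).
#' @return a [niw_params()] with m = colMeans(X), Psi = I,
#'   nu = kappa = D - 1 + 0.001.
#' @export
niw_default_prior <- function(X) {
  D <- ncol(X)
  nu0 <- D - 1 + 0.001
  niw_params(colMeans(X), kappa = nu0, Psi = diag(D), nu = nu0)
}

#' Conjugate NIW posterior update from (weighted) sufficient statistics
#' @param prior a [niw_params()].
#' @param N total responsibility mass.
#' @param xbar weighted mean vector (any value when N = 0).
#' @param S weighted scatter matrix around `xbar`.
#' @return updated [niw_params()].
#' @export
niw_update <- function(prior, N, xbar, S) {
  if (N <= 0) return(prior)
  kappa <- prior$kappa + N
  m <- (prior$kappa * prior$m + N * xbar) / kappa
  dv <- xbar - prior$m
  Psi <- prior$Psi + S + (prior$kappa * N / kappa) * (dv %o% dv)
  niw_params(m, kappa, (Psi + t(Psi)) / 2, prior$nu + N)
}

# E_q[log |Sigma|] under q = NIW(m, kappa, Psi, nu)
niw_e_logdet_sigma <- function(q) {
  logdet_spd(q$Psi) - q$D * log(2) -
    sum(digamma((q$nu + 1 - seq_len(q$D)) / 2))
}

#' Expected Gaussian log density under an NIW factor
#'
#' Returns `E_q[log N(x | mu, Sigma)]` for each row of `X`; exponentiating
#' gives the leaf scores used by the variational parser.
#'
#' @param q a [niw_params()] (the variational factor).
#' @param X n x D matrix.
#' @return numeric vector of length n.
#' @export
niw_e_log_gaussian <- function(q, X) {
  X <- matrix(X, ncol = q$D)
  Pinv <- chol2inv(chol(q$Psi))
  dx <- sweep(X, 2, q$m)
  quad <- rowSums((dx %*% Pinv) * dx)
  -q$D / 2 * log(2 * pi) - 0.5 * niw_e_logdet_sigma(q) -
    0.5 * (q$D / q$kappa + q$nu * quad)
}

# E_q[log NIW(mu, Sigma; par)] where q is the NIW the expectation runs over
e_log_niw <- function(q, par) {
  D <- q$D
  Eld <- niw_e_logdet_sigma(q)
  Pinv <- chol2inv(chol(q$Psi))
  dm <- q$m - par$m
  quad <- D / q$kappa + q$nu * as.numeric(crossprod(dm, Pinv %*% dm))
  gauss <- -D / 2 * log(2 * pi) + D / 2 * log(par$kappa) - 0.5 * Eld -
    par$kappa / 2 * quad
  iw <- par$nu / 2 * logdet_spd(par$Psi) - par$nu * D / 2 * log(2) -
    lmvgamma(par$nu / 2, D) - (par$nu + D + 1) / 2 * Eld -
    0.5 * q$nu * sum(par$Psi * Pinv)
  gauss + iw
}

#' Negative KL divergence from an NIW variational factor to its prior
#' @param q,prior [niw_params()] lists.
#' @return `E_q[log p(mu, Sigma)] - E_q[log q(mu, Sigma)]` (<= 0).
#' @export
niw_neg_kl <- function(q, prior) {
  e_log_niw(q, prior) - e_log_niw(q, q)
}

#' Multivariate Student-t log density
#' @param X n x D matrix of evaluation points.
#' @param mu location vector.
#' @param S positive-definite scale matrix.
#' @param df degrees of freedom.
#' @return numeric vector of length n.
#' @export
mvt_logdensity <- function(X, mu, S, df) {
  D <- length(mu)
  X <- matrix(X, ncol = D)
  R <- chol(S)
  dx <- sweep(X, 2, mu)
  quad <- colSums(forwardsolve(t(R), t(dx))^2)
  lgamma((df + D) / 2) - lgamma(df / 2) - D / 2 * log(df * pi) -
    sum(log(diag(R))) - (df + D) / 2 * log1p(quad / df)
}

#' Student-t posterior predictive log density of an NIW factor
#'
#' The marginal of a new observation after integrating (mu, Sigma) out of
#' `NIW(m, kappa, Psi, nu)`:
#' `t_{nu - D + 1}(m, Psi (kappa + 1) / (kappa (nu - D + 1)))`.
#'
#' @param q a [niw_params()].
#' @param X n x D matrix.
#' @return numeric vector of length n.
#' @export
niw_predictive_logdensity <- function(q, X) {
  df <- q$nu - q$D + 1
  mvt_logdensity(X, q$m, q$Psi * (q$kappa + 1) / (q$kappa * df), df)
}

#' Draw (mu, Sigma) from an NIW distribution
#' @param q a [niw_params()]; uses the current RNG stream.
#' @return list with `mu`, `Sigma`.
#' @export
niw_sample <- function(q) {
  # Bartlett construction (stats::rWishart insists on nu >= D, but the
  # barely-proper prior has nu = D - 1 + 0.001)
  D <- q$D
  L <- t(chol(chol2inv(chol(q$Psi)))) # lower factor of Psi^{-1}
  A <- matrix(0, D, D)
  diag(A) <- sqrt(stats::rchisq(D, df = q$nu - seq_len(D) + 1))
  A[lower.tri(A)] <- stats::rnorm(D * (D - 1) / 2)
  LA <- L %*% A
  W <- LA %*% t(LA) # ~ Wishart(Psi^{-1}, nu)
  # near-singular draws occur at barely-proper dof; regularize the inversion
  Sigma <- chol2inv(chol(W + 1e-8 * diag(D)))
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- q$m + drop(stats::rnorm(q$D) %*% chol(Sigma / q$kappa))
  list(mu = mu, Sigma = Sigma)
}
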