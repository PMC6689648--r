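# HDP-HMM baseline with variable initial state and Gaussian emissions,
# fitted by the same truncated mean-field machinery as the PCFG.
#
# Generative model (truncation K_omega states):
#   omega ~ GEM(alpha) truncated
#   pi_init ~ Dir(alpha * omega); pi_k (transition rows) ~ Dir(alpha * omega)
#   rho_k ~ Beta(1, 1)       per-state stop probability (optional; finite
#                             strings need an explicit stopping mechanism,
#                             mirroring the PCFG's branch/emit switch)
#   (mu_k, Sigma_k) ~ NIW(m0, k0, Psi0, nu0)
# A string emits x_t from its state k_t; after each emission the chain stops
# with probability rho_{k_t} or transitions. With `termination = FALSE` the
# stop factors are dropped and likelihoods are over fixed-length sequences.

#' Hyperparameters of the HDP-HMM
#' @param K_omega state truncation (full-scale default 100).
#' @param alpha DP/GEM concentration (default 1).
#' @param niw optional [niw_params()] emission prior (from data if `NULL`).
#' @param termination model string termination with per-state Beta(1,1)
#'   stop probabilities (`TRUE`) or score fixed-length sequences (`FALSE`).
#' @return an `hmm_hyperparams` list.
#' @export
hmm_hyperparams <- function(K_omega = 100L, alpha = 1, niw = NULL,
                            termination = TRUE) {
  if (K_omega < 1) stop("truncation must be >= 1")
  structure(list(K_omega = as.integer(K_omega), alpha = alpha, niw = niw,
                 termination = isTRUE(termination)),
            class = "hmm_hyperparams")
}

#' Initialize a variational state for the HDP-HMM
#' @param corpus list of feature strings or l x D matrices.
#' @param hyper an [hmm_hyperparams()].
#' @param seed integer seed.
#' @return an `hmm_state`.
#' @export
init_hmm_state <- function(corpus, hyper, seed = 1L) {
  Xs <- as_feature_matrices(corpus)
  Xall <- do.call(rbind, Xs)
  prior <- hyper$niw %||% niw_default_prior(Xall)
  D <- prior$D; K <- hyper$K_omega
  set.seed(seed)
  omega <- rep(1 / K, K)
  jit <- function(a) a * (1 + 0.1 * stats::runif(length(a)))
  sd_pool <- sqrt(mean(apply(Xall, 2, stats::var)))
  if (!is.finite(sd_pool) || sd_pool <= 0) sd_pool <- 1
  structure(list(
    hyper = hyper, prior = prior, D = D, omega = omega,
    dir_init = jit(hyper$alpha * omega),
    dir_trans = matrix(jit(rep(hyper$alpha * omega, each = K)), K, K),
    dir_stop = matrix(jit(rep(1, 2 * K)), K, 2), # [continue, stop]
    niw = lapply(seq_len(K), function(k)
      niw_params(prior$m + stats::rnorm(D, sd = sd_pool), prior$kappa,
                 prior$Psi, prior$nu)),
    elbo_trace = numeric(0)),
    class = "hmm_state")
}

# exp(E[log .]) weights of the current factors
hmm_expected_weights <- function(state) {
  K <- state$hyper$K_omega
  e_dir <- function(d) exp(digamma_safe(d) - digamma_safe(sum(d)))
  tw <- t(apply(state$dir_trans, 1, e_dir))
  if (state$hyper$termination) {
    sw <- exp(digamma_safe(state$dir_stop) -
                digamma_safe(rowSums(state$dir_stop)))
    cont <- sw[, 1]; stp <- sw[, 2]
  } else {
    cont <- rep(1, K); stp <- rep(1, K)
  }
  list(init_w = e_dir(state$dir_init), trans_w = matrix(tw, K, K),
       cont_w = cont, stop_w = stp)
}

hmm_leaf_scores <- function(state, X) {
  ll <- vapply(state$niw, function(q) niw_e_log_gaussian(q, X),
               numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  shift <- apply(ll, 1, max)
  list(score = exp(ll - shift), shift = shift)
}

# scaled forward-backward under arbitrary non-negative weights.
# e: l x K emission scores (already shifted); returns counts and
# log_Z = log sum over state paths (plus sum(shift), added by callers).
hmm_forward_backward <- function(w, e) {
  l <- nrow(e); K <- ncol(e)
  A <- matrix(0, l, K); cs <- numeric(l)
  A[1, ] <- w$init_w * e[1, ]
  cs[1] <- sum(A[1, ])
  if (cs[1] <= 0) stop("string has total weight zero under the HMM")
  A[1, ] <- A[1, ] / cs[1]
  if (l >= 2) for (t in 2:l) {
    A[t, ] <- as.vector(crossprod(w$trans_w, A[t - 1, ] * w$cont_w)) * e[t, ]
    cs[t] <- sum(A[t, ])
    if (cs[t] <= 0) stop("string has total weight zero under the HMM")
    A[t, ] <- A[t, ] / cs[t]
  }
  zl <- sum(A[l, ] * w$stop_w)
  log_Z <- sum(log(cs)) + log(zl)
  B <- matrix(0, l, K)
  B[l, ] <- w$stop_w / zl
  trans_counts <- matrix(0, K, K)
  if (l >= 2) for (t in (l - 1):1) {
    m <- w$trans_w * ((A[t, ] * w$cont_w) %o% (e[t + 1, ] * B[t + 1, ]))
    trans_counts <- trans_counts + m / cs[t + 1]
    B[t, ] <- w$cont_w * as.vector(w$trans_w %*% (e[t + 1, ] * B[t + 1, ])) /
      cs[t + 1]
  }
  resp <- A * B
  resp <- resp / rowSums(resp)
  list(log_Z = log_Z, resp = resp,
       init_counts = resp[1, ], trans_counts = trans_counts,
       cont_counts = if (l >= 2) colSums(resp[-l, , drop = FALSE])
                     else numeric(K),
       stop_counts = resp[l, ])
}

#' Variational E step for the HDP-HMM
#' @param state an `hmm_state`.
#' @param corpus list of feature strings or matrices.
#' @return accumulated expected counts including `log_Z_total`.
#' @export
hmm_e_step <- function(state, corpus) {
  Xs <- as_feature_matrices(corpus)
  K <- state$hyper$K_omega; D <- state$D
  w <- hmm_expected_weights(state)
  lfs <- batch_leaf_scores(state$niw, Xs)
  acc <- list(init = numeric(K), trans = matrix(0, K, K),
              cont = numeric(K), stop = numeric(K),
              N = numeric(K), Sx = matrix(0, K, D),
              Sxx = array(0, c(K, D, D)), log_Z_total = 0,
              n_strings = length(Xs), total_len = 0)
  for (i in seq_along(Xs)) {
    X <- Xs[[i]]
    lf <- lfs[[i]]
    fb <- tryCatch(hmm_forward_backward(w, lf$score), error = function(e)
      stop(sprintf("string %d: %s", i, conditionMessage(e)), call. = FALSE))
    acc$init <- acc$init + fb$init_counts
    acc$trans <- acc$trans + fb$trans_counts
    acc$cont <- acc$cont + fb$cont_counts
    acc$stop <- acc$stop + fb$stop_counts
    acc$log_Z_total <- acc$log_Z_total + fb$log_Z + sum(lf$shift)
    acc$total_len <- acc$total_len + nrow(X)
    r <- fb$resp
    acc$N <- acc$N + colSums(r)
    acc$Sx <- acc$Sx + t(r) %*% X
    for (k in which(colSums(r) > 0))
      acc$Sxx[k, , ] <- acc$Sxx[k, , ] + crossprod(X * sqrt(r[, k]))
  }
  acc
}

#' Variational M step for the HDP-HMM
#' @param state an `hmm_state`.
#' @param stats output of [hmm_e_step()].
#' @return the updated `hmm_state`.
#' @export
hmm_m_step <- function(state, stats) {
  hyper <- state$hyper; K <- hyper$K_omega
  state$dir_init <- hyper$alpha * state$omega + stats$init
  state$dir_trans <- matrix(rep(hyper$alpha * state$omega, each = K), K, K) +
    stats$trans
  if (hyper$termination)
    state$dir_stop <- cbind(1 + stats$cont, 1 + stats$stop)
  for (k in seq_len(K)) {
    N <- stats$N[k]
    if (N > 0) {
      xbar <- stats$Sx[k, ] / N
      S <- stats$Sxx[k, , ] - N * (xbar %o% xbar)
      S <- (S + t(S)) / 2 + 1e-8 * diag(state$D)
      state$niw[[k]] <- niw_update(state$prior, N, xbar, S)
    } else {
      state$niw[[k]] <- state$prior
    }
  }
  dir_init <- state$dir_init; dir_trans <- state$dir_trans
  f_omega <- function(o) {
    v <- gem_log_density(o, hyper$alpha) +
      elbo_dir_prior_term(dir_init, hyper$alpha * o)
    for (k in seq_len(K))
      v <- v + elbo_dir_prior_term(dir_trans[k, ], hyper$alpha * o)
    v
  }
  state$omega <- optimize_sticks(state$omega, f_omega)$beta
  state
}

hmm_prior_elbo_terms <- function(state) {
  hyper <- state$hyper; K <- hyper$K_omega
  base <- hyper$alpha * state$omega
  v <- gem_log_density(state$omega, hyper$alpha) +
    dirichlet_neg_kl(state$dir_init, base)
  for (k in seq_len(K)) {
    v <- v + dirichlet_neg_kl(state$dir_trans[k, ], base)
    if (hyper$termination)
      v <- v + dirichlet_neg_kl(state$dir_stop[k, ], c(1, 1))
  }
  for (q in state$niw) v <- v + niw_neg_kl(q, state$prior)
  v
}

#' Evidence lower bound of an HMM variational state
#' @param state an `hmm_state`.
#' @param corpus list of feature strings or matrices.
#' @return scalar ELBO.
#' @export
hmm_elbo <- function(state, corpus) {
  Xs <- as_feature_matrices(corpus)
  w <- hmm_expected_weights(state)
  lfs <- batch_leaf_scores(state$niw, Xs)
  lz <- sum(vapply(lfs, function(lf)
    hmm_forward_backward(w, lf$score)$log_Z + sum(lf$shift), 0))
  lz + hmm_prior_elbo_terms(state)
}

#' Fit the HDP-HMM by multi-restart coordinate ascent
#'
#' Same restart policy, stopping rule and accepted-ascent stick update as
#' [fit_pcfg()], for a controlled model comparison.
#'
#' @param corpus list of feature strings or l x D matrices.
#' @param hyper an [hmm_hyperparams()].
#' @param cfg a [fit_config()].
#' @return the best `hmm_state` with `$elbo_trace` and `$runs`.
#' @export
fit_hmm <- function(corpus, hyper = hmm_hyperparams(), cfg = fit_config()) {
  if (!length(corpus)) stop("corpus must be nonempty")
  best <- NULL; runs <- list()
  for (r in seq_len(cfg$n_restarts)) {
    sd_r <- child_seed(cfg$seed, r)
    res <- tryCatch({
      state <- init_hmm_state(corpus, hyper, seed = sd_r)
      trace <- numeric(0)
      for (it in seq_len(cfg$max_iter)) {
        stats <- hmm_e_step(state, corpus)
        el <- stats$log_Z_total + hmm_prior_elbo_terms(state)
        trace <- c(trace, el)
        if (it >= 2 && (el - trace[it - 1]) < cfg$tol) break
        state <- hmm_m_step(state, stats)
      }
      state$elbo_trace <- trace
      state
    }, error = function(e) e)
    if (inherits(res, "error")) {
      runs[[r]] <- list(seed = sd_r, error = conditionMessage(res))
      next
    }
    runs[[r]] <- list(seed = sd_r, n_iter = length(res$elbo_trace),
                      final_elbo = res$elbo_trace[length(res$elbo_trace)])
    if (is.null(best) ||
        runs[[r]]$final_elbo > best$elbo_trace[length(best$elbo_trace)])
      best <- res
  }
  if (is.null(best))
    stop("all restarts failed: ",
         paste(vapply(runs, function(x) x$error %||% "", ""), collapse = "; "))
  best$runs <- runs
  best
}

#' Sample a corpus from the HDP-HMM prior
#'
#' @param n number of strings.
#' @param hyper an [hmm_hyperparams()] with an explicit `niw` prior.
#' @param seed integer seed.
#' @param max_len rejection bound on string length (termination mode) or
#'   the fixed length range sampler bound.
#' @return list with `params` (`init_p`, `trans_p`, `stop_p`, `emission`),
#'   `strings` and `paths` (latent state sequences).
#' @export
generate_hmm <- function(n, hyper, seed = 1L, max_len = 50L) {
  if (is.null(hyper$niw)) stop("generation needs an explicit `niw` prior")
  set.seed(seed)
  K <- hyper$K_omega
  omega <- sample_gem(K, hyper$alpha)
  params <- list(
    omega = omega,
    init_p = rdirichlet1(hyper$alpha * omega),
    trans_p = t(vapply(seq_len(K), function(k)
      rdirichlet1(hyper$alpha * omega), numeric(K))),
    stop_p = stats::runif(K),
    emission = lapply(seq_len(K), function(k) niw_sample(hyper$niw)))
  params$trans_p <- matrix(params$trans_p, K, K)
  paths <- lapply(seq_len(n), function(i) {
    repeat {
      k <- sample.int(K, 1, prob = params$init_p)
      path <- k
      while (stats::runif(1) >= params$stop_p[k] && length(path) <= max_len) {
        k <- sample.int(K, 1, prob = params$trans_p[k, ])
        path <- c(path, k)
      }
      if (length(path) <= max_len) return(path)
    }
  })
  D <- length(params$emission[[1]]$mu)
  strings <- lapply(paths, function(p) {
    stack_rows(p, function(k) {
      em <- params$emission[[k]]
      em$mu + drop(stats::rnorm(D) %*% chol(em$Sigma))
    }, D)
  })
  list(params = params, strings = strings, paths = paths)
}

#' Forward log likelihood of a string under fixed HMM parameters
#'
#' @param init_p,trans_p initial distribution and transition matrix.
#' @param stop_p per-state stop probabilities, or `NULL` for fixed-length
#'   scoring.
#' @param leaf_loglik l x K matrix of per-position state log emission
#'   densities.
#' @return scalar log likelihood.
#' @export
hmm_forward_loglik <- function(init_p, trans_p, stop_p, leaf_loglik) {
  K <- length(init_p)
  shift <- apply(leaf_loglik, 1, max)
  w <- list(init_w = init_p, trans_w = trans_p,
            cont_w = if (is.null(stop_p)) rep(1, K) else 1 - stop_p,
            stop_w = if (is.null(stop_p)) rep(1, K) else stop_p)
  hmm_forward_backward(w, exp(leaf_loglik - shift))$log_Z + sum(shift)
}

#' Encode a fixed-parameter HMM as a strictly right-branching PCFG
#'
#' Regular grammars are the PCFGs that only generate left- or
#' right-branching structures; this makes the inclusion executable. The
#' returned weight table uses 2K non-terminals -- a "continue" symbol C_k
#' and an emit-only symbol E_k per state -- with the only non-zero branch
#' rules C_k -> (E_k, C_k'), so every positive-weight parse is
#' right-branching and the inside total equals the HMM forward likelihood.
#'
#' @inheritParams hmm_forward_loglik
#' @return a [rule_weight_table()] over 2K non-terminals and K terminals.
#' @export
hmm_as_right_branching_pcfg <- function(init_p, trans_p, stop_p,
                                        leaf_loglik) {
  K <- length(init_p)
  n <- 2L * K # non-terminals: C_k = k, E_k = K + k
  root_w <- c(init_p, numeric(K))
  if (is.null(stop_p)) {
    bc <- c(rep(1, K), numeric(K))
    ec <- c(rep(1, K), rep(1, K))
  } else {
    bc <- c(1 - stop_p, numeric(K))
    ec <- c(stop_p, rep(1, K))
  }
  branch_w <- array(0, c(n, n, n))
  for (k in seq_len(K)) for (k2 in seq_len(K))
    branch_w[k, K + k, k2] <- trans_p[k, k2]
  emit_w <- matrix(0, n, K)
  for (k in seq_len(K)) {
    emit_w[k, k] <- 1      # C_k emits its own state's terminal (last symbol)
    emit_w[K + k, k] <- 1  # E_k emits its state's terminal
  }
  shift <- apply(leaf_loglik, 1, max)
  rule_weight_table(root_w, bc, ec, branch_w, emit_w,
                    exp(leaf_loglik - shift), shift)
}

#' Posterior predictive log density of a string under a fitted HMM
#'
#' Plug-in estimator: posterior-mean initial/transition/stop probabilities
#' with Student-t emission predictives, summed over state paths by the
#' forward algorithm; `"mc"` averages exact likelihoods over draws from q.
#'
#' @param state a fitted `hmm_state`.
#' @param x one feature string or l x D matrix.
#' @param method `"plugin"` or `"mc"`.
#' @param n_samples Monte Carlo sample count for `"mc"`.
#' @return list with `log_density` and `per_point`.
#' @export
hmm_predictive_logdensity <- function(state, x, method = c("plugin", "mc"),
                                      n_samples = 1000L) {
  method <- match.arg(method)
  X <- as_feature_matrices(list(x))[[1]]
  l <- nrow(X); K <- state$hyper$K_omega
  term <- state$hyper$termination
  if (method == "plugin") {
    ll <- matrix(vapply(state$niw, function(q)
      niw_predictive_logdensity(q, X), numeric(l)), nrow = l)
    ld <- hmm_forward_loglik(
      state$dir_init / sum(state$dir_init),
      state$dir_trans / rowSums(state$dir_trans),
      if (term) state$dir_stop[, 2] / rowSums(state$dir_stop) else NULL,
      ll)
  } else {
    draws <- vapply(seq_len(n_samples), function(i) {
      tp <- t(apply(state$dir_trans, 1, rdirichlet1))
      sp <- if (term) apply(state$dir_stop, 1, function(d)
        stats::rbeta(1, d[2], d[1])) else NULL
      ems <- lapply(state$niw, niw_sample)
      ll <- matrix(vapply(ems, function(e) {
        dx <- sweep(X, 2, e$mu)
        R <- chol(e$Sigma)
        -0.5 * (state$D * log(2 * pi) + 2 * sum(log(diag(R))) +
                  colSums(forwardsolve(t(R), t(dx))^2))
      }, numeric(l)), nrow = l)
      hmm_forward_loglik(rdirichlet1(state$dir_init), matrix(tp, K, K),
                         sp, ll)
    }, 0)
    ld <- logsumexp(draws) - log(n_samples)
  }
  list(log_density = ld, per_point = ld / l)
}
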