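# HDP-PCFG with variable root and Gaussian emission conditioned on
# terminals, fitted by truncated mean-field coordinate ascent.
#
# Generative model (truncations K_beta non-terminals, K_gamma terminals):
#   beta ~ GEM(alpha) truncated; gamma ~ GEM(alpha) truncated
#   phi_root ~ Dir(alpha * beta)                 (variable root label)
#   phi_z_choice ~ Beta(1, 1)                    (branch vs emit, per z)
#   phi_z_branch ~ Dir(alpha_branch * beta beta') over label pairs
#   phi_z_emit ~ Dir(alpha_emit * gamma)         over terminals
#   (mu_s, Sigma_s) ~ NIW(m0, k0, Psi0, nu0)     per terminal s
# A parse grows from the root by branch/emit choices; each terminal emits a
# D-dimensional feature vector from its Gaussian.
#
# The variational posterior factorizes over all of the above with Dirichlet,
# Beta(= 2-dim Dirichlet), NIW and (for the sticks) degenerate point-mass
# factors; q(tau) over parses is implied by exp(E[log p]) weights.

#' Hyperparameters of the HDP-PCFG
#'
#' Defaults: every concentration equal to 1; NIW prior with
#' identity scale, nu0 = kappa0 = D - 1 + 0.001, and m0 equal to the sample
#' mean of the training vectors (filled in at fitting time when `niw` is
#' `NULL`); truncations K_beta = 40, K_gamma = 100 (tests use smaller
#' desk-scale values).
#'
#' @param K_beta non-terminal truncation.
#' @param K_gamma terminal truncation.
#' @param alpha,alpha_branch,alpha_emit DP/GEM concentrations.
#' @param niw optional [niw_params()] prior; computed from the data when
#'   `NULL`.
#' @return a `pcfg_hyperparams` list.
#' @export
pcfg_hyperparams <- function(K_beta = 40L, K_gamma = 100L, alpha = 1,
                             alpha_branch = 1, alpha_emit = 1, niw = NULL) {
  if (K_beta < 1 || K_gamma < 1) stop("truncations must be >= 1")
  structure(list(K_beta = as.integer(K_beta), K_gamma = as.integer(K_gamma),
                 alpha = alpha, alpha_branch = alpha_branch,
                 alpha_emit = alpha_emit, niw = niw),
            class = "pcfg_hyperparams")
}

#' Fitting configuration for the variational optimizers
#'
#' Full-scale analysis uses 500 restarts, tolerance 0.1 and 300 maximum
#' iterations; the defaults here are the same tolerance and cap with a
#' desk-scale restart count.
#'
#' @param n_restarts number of random initializations (best ELBO wins).
#' @param tol stop when the ELBO improves by less than this.
#' @param max_iter sweep cap per restart.
#' @param seed master seed; restart r uses a derived child seed.
#' @return a `fit_config` list.
#' @export
fit_config <- function(n_restarts = 10L, tol = 0.1, max_iter = 300L,
                       seed = 1L) {
  if (n_restarts < 1 || tol <= 0) stop("need n_restarts >= 1 and tol > 0")
  list(n_restarts = as.integer(n_restarts), tol = tol,
       max_iter = as.integer(max_iter), seed = as.integer(seed))
}

# normalize a corpus to a list of l x D feature matrices
as_feature_matrices <- function(corpus) {
  lapply(corpus, function(s) {
    if (inherits(s, "feature_string")) s$vectors
    else as.matrix(s)
  })
}

rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = a)
  if (sum(g) <= 0) { g <- numeric(length(a)); g[which.max(a)] <- 1 }
  g / sum(g)
}

pcfg_base_counts <- function(hyper, beta, gamma) {
  K <- length(beta); Kg <- length(gamma)
  list(root = hyper$alpha * beta,
       choice = c(1, 1),
       branch = hyper$alpha_branch * outer(beta, beta), # [y1, y2], same all z
       emit = hyper$alpha_emit * gamma)
}

#' Initialize a variational state for the HDP-PCFG
#'
#' Sticks start uniform; Dirichlet pseudo-counts are the prior base counts
#' with small multiplicative uniform jitter; NIW means are jittered around
#' the prior mean by Gaussian noise at the pooled per-dimension scale of the
#' data. Deterministic given `seed`.
#'
#' @param corpus list of feature strings or l x D matrices.
#' @param hyper a [pcfg_hyperparams()].
#' @param seed integer seed.
#' @param style `"random"` for unstructured jitter, or `"chain"` to seed
#'   the branch pseudo-counts toward self-recursive chain rules
#'   `z -> (y, z)` (the regular-grammar basin, using the package's global
#'   right-branching convention). Multi-restart fitting cycles both styles
#'   so that qualitatively different ELBO basins are all visited; the
#'   best-ELBO selection then decides between them on the evidence.
#' @return a `pcfg_state`.
#' @export
init_pcfg_state <- function(corpus, hyper, seed = 1L,
                            style = c("random", "chain")) {
  style <- match.arg(style)
  Xs <- as_feature_matrices(corpus)
  Xall <- do.call(rbind, Xs)
  prior <- hyper$niw %||% niw_default_prior(Xall)
  D <- prior$D
  K <- hyper$K_beta; Kg <- hyper$K_gamma
  set.seed(seed)
  beta <- rep(1 / K, K); gamma <- rep(1 / Kg, Kg)
  bc <- pcfg_base_counts(hyper, beta, gamma)
  jit <- function(a) a * (1 + 0.1 * stats::runif(length(a)))
  sd_pool <- sqrt(mean(apply(Xall, 2, stats::var)))
  if (!is.finite(sd_pool) || sd_pool <= 0) sd_pool <- 1
  # emission means start at randomly chosen data vectors (mixture-model
  # practice: keeps components on the data manifold)
  picks <- sample.int(nrow(Xall), Kg, replace = nrow(Xall) < Kg)
  niw <- lapply(seq_len(Kg), function(s)
    niw_params(Xall[picks[s], ] +
                 stats::rnorm(D, sd = 0.1 * sd_pool), prior$kappa,
               prior$Psi, prior$nu))
  dir_branch <- array(jit(rep(as.vector(bc$branch), each = K)), c(K, K, K))
  if (style == "chain") {
    boost <- sum(vapply(Xs, nrow, 0L)) / (K * K)
    for (z in seq_len(K)) dir_branch[z, , z] <- dir_branch[z, , z] + boost
  }
  structure(list(
    hyper = hyper, prior = prior, D = D, beta = beta, gamma = gamma,
    dir_root = jit(bc$root),
    dir_choice = matrix(jit(rep(bc$choice, each = K)), K, 2),
    dir_branch = dir_branch,
    dir_emit = matrix(jit(rep(bc$emit, each = K)), K, Kg, byrow = FALSE),
    niw = niw, elbo_trace = numeric(0)),
    class = "pcfg_state")
}

#' Rule weights exp(E_q[log phi]) of a variational state
#'
#' Expected-log-probability weights of every rule under the current
#' Dirichlet factors (digamma differences, exponentiated); these populate a
#' [rule_weight_table()] once a string's leaf scores are attached.
#'
#' @param state a `pcfg_state`.
#' @return list with `root_w`, `branch_choice_w`, `emit_choice_w`,
#'   `branch_w` (K x K x K), `emit_w` (K x Kg).
#' @export
expected_log_weights <- function(state) {
  K <- state$hyper$K_beta
  e_dir <- function(d) exp(digamma_safe(d) - digamma_safe(sum(d)))
  br <- state$dir_branch
  brw <- array(0, dim(br))
  for (z in seq_len(K)) {
    dz <- br[z, , ]
    brw[z, , ] <- exp(digamma_safe(dz) - digamma_safe(sum(dz)))
  }
  ch <- exp(digamma_safe(state$dir_choice) -
              digamma_safe(rowSums(state$dir_choice)))
  list(root_w = e_dir(state$dir_root),
       branch_choice_w = ch[, 1], emit_choice_w = ch[, 2],
       branch_w = brw,
       emit_w = exp(digamma_safe(state$dir_emit) -
                      digamma_safe(rowSums(state$dir_emit))))
}

# expected-log Gaussian leaf scores for one string, shifted per position
pcfg_leaf_scores <- function(state, X) {
  ll <- vapply(state$niw, function(q) niw_e_log_gaussian(q, X),
               numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  shift <- apply(ll, 1, max)
  list(score = exp(ll - shift), shift = shift)
}

# leaf scores for a whole corpus in one pass over the stacked vectors
# (one Cholesky per factor per sweep instead of per string)
batch_leaf_scores <- function(niw_list, Xs) {
  Xall <- do.call(rbind, Xs)
  ll <- vapply(niw_list, function(q) niw_e_log_gaussian(q, Xall),
               numeric(nrow(Xall)))
  ll <- matrix(ll, nrow = nrow(Xall))
  ends <- cumsum(vapply(Xs, nrow, 0L))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(Xs), function(i) {
    li <- ll[starts[i]:ends[i], , drop = FALSE]
    shift <- apply(li, 1, max)
    list(score = exp(li - shift), shift = shift)
  })
}

#' Build the variational parse table for one string
#' @param state a `pcfg_state`.
#' @param X l x D feature matrix.
#' @param rw optional precomputed [expected_log_weights()].
#' @return a [rule_weight_table()].
#' @export
pcfg_string_table <- function(state, X, rw = NULL) {
  rw <- rw %||% expected_log_weights(state)
  lf <- pcfg_leaf_scores(state, X)
  rule_weight_table(rw$root_w, rw$branch_choice_w, rw$emit_choice_w,
                    rw$branch_w, rw$emit_w, lf$score, lf$shift)
}

#' Variational E step: expected rule counts over a corpus
#'
#' Runs inside-outside under the exp(E[log phi]) weights for every string
#' and accumulates expected counts of root choices, branch/emit decisions,
#' branch pairs and terminal emissions, plus the Gaussian sufficient
#' statistics of the per-position terminal responsibilities.
#'
#' @param state a `pcfg_state`.
#' @param corpus list of feature strings or matrices.
#' @return list of accumulated statistics including `log_Z_total`.
#' @export
pcfg_e_step <- function(state, corpus) {
  Xs <- as_feature_matrices(corpus)
  K <- state$hyper$K_beta; Kg <- state$hyper$K_gamma; D <- state$D
  rw <- expected_log_weights(state)
  lfs <- batch_leaf_scores(state$niw, Xs)
  acc <- list(root = numeric(K), choice = matrix(0, K, 2),
              branch = array(0, c(K, K, K)), emit = matrix(0, K, Kg),
              N = numeric(Kg), Sx = matrix(0, Kg, D),
              Sxx = array(0, c(Kg, D, D)), log_Z_total = 0,
              n_strings = length(Xs), total_len = 0)
  for (i in seq_along(Xs)) {
    X <- Xs[[i]]
    wt <- rule_weight_table(rw$root_w, rw$branch_choice_w, rw$emit_choice_w,
                            rw$branch_w, rw$emit_w, lfs[[i]]$score,
                            lfs[[i]]$shift)
    io <- tryCatch(inside_outside_counts(wt), error = function(e)
      stop(sprintf("string %d: %s", i, conditionMessage(e)), call. = FALSE))
    acc$root <- acc$root + io$root_counts
    acc$choice <- acc$choice + cbind(io$branch_choice_counts,
                                     io$emit_choice_counts)
    acc$branch <- acc$branch + io$branch_counts
    acc$emit <- acc$emit + io$emit_counts
    acc$log_Z_total <- acc$log_Z_total + io$log_Z
    acc$total_len <- acc$total_len + nrow(X)
    r <- io$resp
    acc$N <- acc$N + colSums(r)
    acc$Sx <- acc$Sx + t(r) %*% X
    for (s in which(colSums(r) > 0))
      acc$Sxx[s, , ] <- acc$Sxx[s, , ] + crossprod(X * sqrt(r[, s]))
  }
  acc
}

#' Variational M step: conjugate factor updates plus stick re-optimization
#'
#' Dirichlet parameters become prior base counts (alpha * beta for the root,
#' alpha_branch * beta_B * beta_C for branch pairs, alpha_emit * gamma for
#' emissions, Beta(1,1) for the choice) plus expected counts; NIW factors
#' get the standard conjugate update from the responsibilities; the
#' degenerate sticks beta and gamma are re-optimized by accepted ascent on
#' their ELBO terms.
#'
#' @param state a `pcfg_state`.
#' @param stats output of [pcfg_e_step()].
#' @return the updated `pcfg_state`.
#' @export
pcfg_m_step <- function(state, stats) {
  hyper <- state$hyper
  K <- hyper$K_beta; Kg <- hyper$K_gamma
  bc <- pcfg_base_counts(hyper, state$beta, state$gamma)
  state$dir_root <- bc$root + stats$root
  state$dir_choice <- matrix(rep(bc$choice, each = K), K, 2) + stats$choice
  db <- array(0, c(K, K, K))
  for (z in seq_len(K)) db[z, , ] <- bc$branch + stats$branch[z, , ]
  state$dir_branch <- db
  state$dir_emit <- matrix(rep(bc$emit, each = K), K, Kg) + stats$emit
  for (s in seq_len(Kg)) {
    N <- stats$N[s]
    if (N > 0) {
      xbar <- stats$Sx[s, ] / N
      S <- stats$Sxx[s, , ] - N * (xbar %o% xbar)
      S <- (S + t(S)) / 2 + 1e-8 * diag(state$D)
      state$niw[[s]] <- niw_update(state$prior, N, xbar, S)
    } else {
      state$niw[[s]] <- state$prior
    }
  }
  # degenerate stick updates (accepted ascent on the beta/gamma ELBO terms)
  dir_root <- state$dir_root; dir_branch <- state$dir_branch
  f_beta <- function(b) {
    v <- gem_log_density(b, hyper$alpha) +
      elbo_dir_prior_term(dir_root, hyper$alpha * b)
    bb <- hyper$alpha_branch * as.vector(outer(b, b))
    for (z in seq_len(K))
      v <- v + elbo_dir_prior_term(as.vector(dir_branch[z, , ]), bb)
    v
  }
  state$beta <- optimize_sticks(state$beta, f_beta)$beta
  dir_emit <- state$dir_emit
  f_gamma <- function(g) {
    v <- gem_log_density(g, hyper$alpha)
    for (z in seq_len(K))
      v <- v + elbo_dir_prior_term(dir_emit[z, ], hyper$alpha_emit * g)
    v
  }
  state$gamma <- optimize_sticks(state$gamma, f_gamma)$beta
  state
}

# ELBO pieces that do not involve the data: -KL of every parametric factor
# from its prior plus the log density of the degenerate sticks
pcfg_prior_elbo_terms <- function(state) {
  hyper <- state$hyper
  K <- hyper$K_beta
  bc <- pcfg_base_counts(hyper, state$beta, state$gamma)
  v <- gem_log_density(state$beta, hyper$alpha) +
    gem_log_density(state$gamma, hyper$alpha) +
    dirichlet_neg_kl(state$dir_root, bc$root)
  for (z in seq_len(K)) {
    v <- v + dirichlet_neg_kl(state$dir_choice[z, ], bc$choice) +
      dirichlet_neg_kl(as.vector(state$dir_branch[z, , ]),
                       as.vector(bc$branch)) +
      dirichlet_neg_kl(state$dir_emit[z, ], bc$emit)
  }
  for (q in state$niw) v <- v + niw_neg_kl(q, state$prior)
  v
}

#' Evidence lower bound of a variational state on a corpus
#'
#' `sum_strings log Z` under the exp(E[log phi]) weights (the optimum of the
#' parse factor q(tau)) plus the negative KL of every parametric factor from
#' its prior and the log prior density of the degenerate sticks. Improvement
#' in this quantity is the stopping statistic (KL improvements with the
#' sign flipped).
#'
#' @param state a `pcfg_state`.
#' @param corpus list of feature strings or matrices.
#' @return scalar ELBO.
#' @export
pcfg_elbo <- function(state, corpus) {
  Xs <- as_feature_matrices(corpus)
  rw <- expected_log_weights(state)
  lfs <- batch_leaf_scores(state$niw, Xs)
  lz <- sum(vapply(seq_along(Xs), function(i)
    inside_log_normalizer(rule_weight_table(
      rw$root_w, rw$branch_choice_w, rw$emit_choice_w, rw$branch_w,
      rw$emit_w, lfs[[i]]$score, lfs[[i]]$shift)), 0))
  lz + pcfg_prior_elbo_terms(state)
}

#' Fit the HDP-PCFG by multi-restart coordinate ascent
#'
#' Each restart initializes from its own child seed and sweeps
#' E step / M step until the ELBO improves by less than `cfg$tol` or
#' `cfg$max_iter` sweeps are reached; the restart with the best final ELBO
#' is returned, with per-restart logs attached.
#'
#' @param corpus list of feature strings or l x D matrices.
#' @param hyper a [pcfg_hyperparams()].
#' @param cfg a [fit_config()].
#' @return the best `pcfg_state`; `$elbo_trace` holds its per-sweep ELBO and
#'   `$runs` the per-restart summaries.
#' @export
fit_pcfg <- function(corpus, hyper = pcfg_hyperparams(), cfg = fit_config()) {
  if (!length(corpus)) stop("corpus must be nonempty")
  best <- NULL; runs <- list()
  for (r in seq_len(cfg$n_restarts)) {
    sd_r <- child_seed(cfg$seed, r)
    res <- tryCatch({
      state <- init_pcfg_state(corpus, hyper, seed = sd_r,
                               style = if (r %% 2 == 0) "chain" else "random")
      trace <- numeric(0)
      for (it in seq_len(cfg$max_iter)) {
        stats <- pcfg_e_step(state, corpus)
        el <- stats$log_Z_total + pcfg_prior_elbo_terms(state)
        trace <- c(trace, el)
        if (it >= 2 && (el - trace[it - 1]) < cfg$tol) break
        state <- pcfg_m_step(state, stats)
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

#' Sample a corpus from the HDP-PCFG prior
#'
#' Draws truncated sticks, Dirichlet rule probabilities and NIW Gaussian
#' parameters from the prior, then generates strings with their latent parse
#' trees. Strings longer than `max_len` are rejected and redrawn.
#'
#' @param n number of strings.
#' @param hyper a [pcfg_hyperparams()]; its `niw` prior must be set (it
#'   supplies D).
#' @param seed integer seed.
#' @param max_len rejection bound on string length.
#' @return list with `params` (the drawn grammar), `strings` (list of l x D
#'   matrices) and `trees` (latent parses).
#' @export
generate_pcfg <- function(n, hyper, seed = 1L, max_len = 25L) {
  if (is.null(hyper$niw)) stop("generation needs an explicit `niw` prior")
  set.seed(seed)
  K <- hyper$K_beta; Kg <- hyper$K_gamma
  beta <- sample_gem(K, hyper$alpha)
  gamma <- sample_gem(Kg, hyper$alpha)
  params <- list(
    beta = beta, gamma = gamma,
    root_p = rdirichlet1(hyper$alpha * beta),
    choice_p = stats::runif(K), # P(branch) per non-terminal
    branch_p = t(vapply(seq_len(K), function(z)
      rdirichlet1(hyper$alpha_branch * as.vector(outer(beta, beta))),
      numeric(K * K))),
    emit_p = t(vapply(seq_len(K), function(z)
      rdirichlet1(hyper$alpha_emit * gamma), numeric(Kg))),
    emission = lapply(seq_len(Kg), function(s) niw_sample(hyper$niw)))
  params$branch_p <- matrix(params$branch_p, K, K * K)
  params$emit_p <- matrix(params$emit_p, K, Kg)
  sample_string <- function() {
    repeat {
      nleaf <- 0L; overflow <- FALSE
      grow <- function(z, depth = 1L) {
        if (overflow) return(NULL)
        # a binary tree of depth d has more than d leaves, so this depth
        # guard only rejects strings the leaf bound would reject anyway
        if (depth > max_len + 1L) { overflow <<- TRUE; return(NULL) }
        if (stats::runif(1) < params$choice_p[z]) { # branch
          pair <- sample.int(K * K, 1, prob = params$branch_p[z, ])
          y1 <- (pair - 1) %% K + 1; y2 <- (pair - 1) %/% K + 1
          lt <- grow(y1, depth + 1L); rt <- grow(y2, depth + 1L)
          if (overflow) return(NULL)
          branch_node(lt, rt, z = as.integer(z))
        } else {
          nleaf <<- nleaf + 1L
          if (nleaf > max_len) { overflow <<- TRUE; return(NULL) }
          s <- sample.int(Kg, 1, prob = params$emit_p[z, ])
          emit_node(0L, z = as.integer(z), s = as.integer(s))
        }
      }
      r <- sample.int(K, 1, prob = params$root_p)
      tree <- grow(r)
      if (!overflow) return(tree)
    }
  }
  assign_pos <- function(tree) {
    p <- 0L
    rec <- function(nd) {
      if (nd$kind == "emit") { p <<- p + 1L; nd$pos <- p; nd }
      else { nd$left <- rec(nd$left); nd$right <- rec(nd$right); nd }
    }
    rec(tree)
  }
  trees <- lapply(seq_len(n), function(i) assign_pos(sample_string()))
  D <- length(params$emission[[1]]$mu)
  strings <- lapply(trees, function(tr) {
    ss <- vapply(enumerate_leaves(tr), function(nd) nd$s, 0L)
    stack_rows(ss, function(s) {
      em <- params$emission[[s]]
      em$mu + drop(stats::rnorm(D) %*% chol(em$Sigma))
    }, D)
  })
  list(params = params, strings = strings, trees = trees)
}

#' Leaves of a parse tree in order
#' @keywords internal
enumerate_leaves <- function(tree) {
  if (tree$kind == "emit") list(tree)
  else c(enumerate_leaves(tree$left), enumerate_leaves(tree$right))
}

#' Posterior predictive log density of a string under a fitted PCFG
#'
#' Default plug-in estimator: posterior-mean rule probabilities with the NIW
#' factors' Student-t predictive densities at the leaves, summed over parses
#' by the inside algorithm. The `"mc"` estimator instead averages the exact
#' string likelihood over draws of the parameters from q (log of the Monte
#' Carlo mean), as a fidelity cross-check.
#'
#' @param state a fitted `pcfg_state`.
#' @param x one feature string or l x D matrix.
#' @param method `"plugin"` or `"mc"`.
#' @param n_samples Monte Carlo sample count for `"mc"`.
#' @return list with `log_density` and `per_point` (= log_density / l).
#' @export
posterior_predictive_logdensity <- function(state, x,
                                            method = c("plugin", "mc"),
                                            n_samples = 1000L) {
  method <- match.arg(method)
  X <- as_feature_matrices(list(x))[[1]]
  l <- nrow(X)
  K <- state$hyper$K_beta; Kg <- state$hyper$K_gamma
  norm1 <- function(v) v / sum(v)
  if (method == "plugin") {
    brw <- array(0, c(K, K, K))
    for (z in seq_len(K))
      brw[z, , ] <- state$dir_branch[z, , ] / sum(state$dir_branch[z, , ])
    chp <- state$dir_choice / rowSums(state$dir_choice)
    ll <- vapply(state$niw, function(q) niw_predictive_logdensity(q, X),
                 numeric(l))
    ll <- matrix(ll, nrow = l)
    shift <- apply(ll, 1, max)
    wt <- rule_weight_table(norm1(state$dir_root), chp[, 1], chp[, 2], brw,
                            state$dir_emit / rowSums(state$dir_emit),
                            exp(ll - shift), shift)
    ld <- inside_log_normalizer(wt)
  } else {
    draws <- vapply(seq_len(n_samples), function(i) {
      brw <- array(0, c(K, K, K))
      for (z in seq_len(K))
        brw[z, , ] <- rdirichlet1(as.vector(state$dir_branch[z, , ]))
      chp <- t(apply(state$dir_choice, 1, rdirichlet1))
      emw <- t(apply(state$dir_emit, 1, rdirichlet1))
      ems <- lapply(state$niw, niw_sample)
      ll <- vapply(ems, function(e) {
        dx <- sweep(X, 2, e$mu)
        R <- chol(e$Sigma)
        -0.5 * (state$D * log(2 * pi) + 2 * sum(log(diag(R))) +
                  colSums(forwardsolve(t(R), t(dx))^2))
      }, numeric(l))
      ll <- matrix(ll, nrow = l)
      shift <- apply(ll, 1, max)
      wt <- rule_weight_table(rdirichlet1(state$dir_root), chp[, 1],
                              chp[, 2], brw, emw, exp(ll - shift), shift)
      inside_log_normalizer(wt)
    }, 0)
    ld <- logsumexp(draws) - log(n_samples)
  }
  list(log_density = ld, per_point = ld / l)
}
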