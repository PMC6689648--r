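# HDP-PCFG: generation, expected-log weights, CAVI updates, ELBO and
# predictive density.

test_that("generation is seed-reproducible and respects truncations", {
  hy <- pcfg_hyperparams(K_beta = 2, K_gamma = 2,
                         niw = niw_params(c(0, 0), 5, diag(2), 5))
  g1 <- generate_pcfg(15, hy, seed = 9)
  g2 <- generate_pcfg(15, hy, seed = 9)
  expect_identical(g1$strings, g2$strings)
  expect_identical(lapply(g1$trees, tree_to_bracket),
                   lapply(g2$trees, tree_to_bracket))
  for (tr in g1$trees) validate_tree(tr)
  # K = 1 truncations: every label is 1
  hy1 <- pcfg_hyperparams(K_beta = 1, K_gamma = 1,
                          niw = niw_params(0, 5, diag(1), 5))
  g <- generate_pcfg(10, hy1, seed = 3)
  labs <- unlist(lapply(g$trees, function(tr) {
    rec <- function(nd) c(nd$z, if (nd$kind == "branch")
      c(rec(nd$left), rec(nd$right)))
    rec(tr)
  }))
  expect_true(all(labs == 1L))
  expect_error(generate_pcfg(5, pcfg_hyperparams(K_beta = 2, K_gamma = 2)),
               "niw")
})

test_that("generated emissions obey the drawn Gaussian parameters", {
  hy <- pcfg_hyperparams(K_beta = 1, K_gamma = 1,
                         niw = niw_params(c(1, -2), 50, diag(2), 30))
  g <- generate_pcfg(1500, hy, seed = 12, max_len = 8)
  X <- do.call(rbind, g$strings)
  mu <- g$params$emission[[1]]$mu
  se <- sqrt(diag(g$params$emission[[1]]$Sigma) / nrow(X))
  expect_true(all(abs(colMeans(X) - mu) < 5 * se + 1e-3))
})

test_that("expected_log_weights has the Dirichlet closed forms", {
  corpus <- toy_cluster_corpus(10, seed = 2)
  st <- init_pcfg_state(corpus, pcfg_hyperparams(K_beta = 3, K_gamma = 3),
                        seed = 5)
  # symmetric Dirichlet -> equal weights
  st$dir_root <- rep(2, 3)
  rw <- expected_log_weights(st)
  expect_equal(rw$root_w, rep(rw$root_w[1], 3))
  # digamma closed form
  st$dir_root <- c(1.3, 2.2, 0.7)
  rw <- expected_log_weights(st)
  expect_equal(log(rw$root_w),
               digamma(st$dir_root) - digamma(sum(st$dir_root)),
               tolerance = 1e-12)
  # Jensen: exp(E log phi) <= posterior mean probability
  expect_true(all(rw$root_w <= st$dir_root / sum(st$dir_root) + 1e-12))
  expect_true(all(rw$emit_w <=
                    st$dir_emit / rowSums(st$dir_emit) + 1e-12))
})

test_that("e_step counts satisfy forced-derivation and conservation laws", {
  corpus2 <- list(matrix(c(0, 0, 1, 1), 2, 2)) # one string, l = 2
  st <- init_pcfg_state(corpus2, pcfg_hyperparams(K_beta = 1, K_gamma = 1),
                        seed = 1)
  stats <- pcfg_e_step(st, corpus2)
  expect_equal(sum(stats$branch), 1, tolerance = 1e-9)   # one branch node
  expect_equal(sum(stats$emit), 2, tolerance = 1e-9)     # two emissions
  expect_equal(stats$choice[1, 1], 1, tolerance = 1e-9)
  expect_equal(stats$choice[1, 2], 2, tolerance = 1e-9)
  corpus <- toy_cluster_corpus(12, seed = 3)
  st <- init_pcfg_state(corpus, pcfg_hyperparams(K_beta = 3, K_gamma = 4),
                        seed = 2)
  stats <- pcfg_e_step(st, corpus)
  tot <- sum(vapply(corpus, nrow, 0L))
  expect_equal(sum(stats$emit), tot, tolerance = 1e-8)
  expect_equal(sum(stats$N), tot, tolerance = 1e-8)
  expect_equal(sum(stats$root), length(corpus), tolerance = 1e-9)
})

test_that("m_step restores base counts at zero statistics", {
  corpus <- toy_cluster_corpus(8, seed = 4)
  hy <- pcfg_hyperparams(K_beta = 2, K_gamma = 2)
  st <- init_pcfg_state(corpus, hy, seed = 3)
  z <- pcfg_e_step(st, corpus)
  z$root[] <- 0; z$choice[] <- 0; z$branch[] <- 0; z$emit[] <- 0
  z$N[] <- 0
  bc <- pcfg_base_counts(hy, st$beta, st$gamma) # beta at update time
  st2 <- pcfg_m_step(st, z)
  expect_equal(st2$dir_root, bc$root, tolerance = 1e-12)
  expect_equal(st2$dir_choice[1, ], bc$choice, tolerance = 1e-12)
  expect_equal(st2$dir_emit[2, ], bc$emit, tolerance = 1e-12)
  # NIW with zero mass returns the prior
  expect_equal(st2$niw[[1]]$m, st2$prior$m)
})

test_that("NIW single-observation update matches the conjugate closed form", {
  pr <- niw_params(c(0, 0), 2, diag(2), 3)
  up <- niw_update(pr, 1, c(4, 0), matrix(0, 2, 2))
  expect_equal(up$m, c(4 / 3, 0), tolerance = 1e-12) # (k0 m0 + x)/(k0 + 1)
  expect_equal(up$kappa, 3)
  expect_equal(up$nu, 4)
})

test_that("CAVI sweeps never decrease the ELBO", {
  corpus <- toy_cluster_corpus(15, seed = 6)
  st <- init_pcfg_state(corpus, pcfg_hyperparams(K_beta = 3, K_gamma = 3),
                        seed = 8)
  trace <- numeric(0)
  for (it in 1:10) {
    stats <- pcfg_e_step(st, corpus)
    trace <- c(trace, stats$log_Z_total + pcfg_prior_elbo_terms(st))
    st <- pcfg_m_step(st, stats)
  }
  expect_true(all(diff(trace) > -1e-6))
  # pcfg_elbo() agrees with the trace bookkeeping
  stats <- pcfg_e_step(st, corpus)
  expect_equal(pcfg_elbo(st, corpus),
               stats$log_Z_total + pcfg_prior_elbo_terms(st),
               tolerance = 1e-8)
})

test_that("fit_pcfg honours the restart and stopping policy", {
  corpus <- toy_cluster_corpus(10, seed = 7)
  hy <- pcfg_hyperparams(K_beta = 2, K_gamma = 2)
  # huge tolerance: exactly one sweep per restart
  one <- fit_pcfg(corpus, hy, fit_config(n_restarts = 1, tol = 1e9,
                                         max_iter = 50, seed = 2))
  expect_length(one$elbo_trace, 2L)
  fit <- fit_pcfg(corpus, hy, fit_config(n_restarts = 3, tol = 0.5,
                                         max_iter = 30, seed = 2))
  finals <- vapply(fit$runs, function(r) r$final_elbo, 0)
  expect_equal(fit$elbo_trace[length(fit$elbo_trace)], max(finals))
  expect_true(all(diff(fit$elbo_trace) > -1e-6))
  expect_error(fit_pcfg(list(), hy), "nonempty")
})

test_that("plug-in predictive matches closed forms and the MC estimator", {
  corpus <- toy_cluster_corpus(10, seed = 8)
  # l = 1, single terminal: P(emit) x multivariate Student-t
  st1 <- init_pcfg_state(corpus, pcfg_hyperparams(K_beta = 1, K_gamma = 1),
                         seed = 2)
  x1 <- matrix(c(1, 2), 1, 2)
  pp <- posterior_predictive_logdensity(st1, x1)
  p_emit <- st1$dir_choice[1, 2] / sum(st1$dir_choice[1, ])
  expect_equal(pp$log_density,
               log(p_emit) + niw_predictive_logdensity(st1$niw[[1]], x1),
               tolerance = 1e-9)
  expect_equal(pp$per_point, pp$log_density)
  # per-point value is total / l
  fit <- fit_pcfg(corpus, pcfg_hyperparams(K_beta = 2, K_gamma = 2),
                  fit_config(n_restarts = 1, tol = 0.5, max_iter = 20,
                             seed = 4))
  pp4 <- posterior_predictive_logdensity(fit, corpus[[1]])
  expect_equal(pp4$per_point, pp4$log_density / nrow(corpus[[1]]))
  # MC cross-check on the l = 1 toy (plug-in is exact there)
  set.seed(99)
  reps <- replicate(8, posterior_predictive_logdensity(
    st1, x1, method = "mc", n_samples = 150)$log_density)
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - pp$log_density), 4 * se + 0.02)
})

test_that("multivariate Student-t density integrates Gaussian tails", {
  # against the univariate closed form from stats::dt
  x <- matrix(seq(-3, 3, by = 1.5), ncol = 1)
  got <- mvt_logdensity(x, mu = 0.5, S = matrix(2), df = 5)
  want <- stats::dt((x - 0.5) / sqrt(2), df = 5, log = TRUE) - log(sqrt(2))
  expect_equal(got, as.vector(want), tolerance = 1e-12)
})
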