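# Posterior diagnostics: parse-count reports, uniform baseline, rule
# frequencies, type counts and the comparison report.

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corpus <- toy_cluster_corpus(20, seed = 21)
      fit <- fit_pcfg(corpus, pcfg_hyperparams(K_beta = 3, K_gamma = 3),
                      fit_config(n_restarts = 2, tol = 0.2, max_iter = 40,
                                 seed = 22))
      cache <<- list(corpus = corpus, fit = fit)
    }
    cache
  }
})

test_that("per-string parse-category masses sum to one", {
  sf <- small_fit()
  rep <- expected_parse_counts(sf$fit, sf$corpus)
  expect_equal(sum(rep$totals), rep$N_l_ge_3, tolerance = 1e-6)
  expect_identical(rep$N, length(sf$corpus))
  expect_identical(rep$short_strings + rep$N_l_ge_3, rep$N)
  # optimal mass cannot exceed the category total
  expect_true(all(rep$optimal <= rep$totals + 1e-9))
  expect_true(rep$pct_nonregular >= 0 && rep$pct_nonregular <= 100)
})

test_that("NONREGULAR mass is zero for l = 3 strings", {
  sf <- small_fit()
  rw <- expected_log_weights(sf$fit)
  three <- Filter(function(X) nrow(X) == 3, sf$corpus)
  for (X in three) {
    wt <- pcfg_string_table(sf$fit, X, rw)
    logZ <- inside_log_normalizer(wt)
    pl <- exp(topology_log_weight(wt, regular_tree(3, "LEFT")) - logZ)
    pr <- exp(topology_log_weight(wt, regular_tree(3, "RIGHT")) - logZ)
    expect_equal(pl + pr, 1, tolerance = 1e-9)
  }
})

test_that("uniform baseline is the summed reciprocal Catalan count", {
  one4 <- list(matrix(0, 4, 2))
  expect_equal(uniform_baseline(one4), 0.2)       # 1/5
  expect_equal(uniform_baseline(list(matrix(0, 3, 2))), 0.5) # 1/2
  expect_equal(uniform_baseline(list(matrix(0, 2, 2))), 0)   # short string
  corpus <- toy_cluster_corpus(15, seed = 23)
  ls <- vapply(corpus, nrow, 0L)
  expect_equal(uniform_baseline(corpus),
               sum(1 / vapply(ls[ls >= 3], count_parses, 0)),
               tolerance = 1e-12)
  # adding strings never decreases the baseline
  expect_gte(uniform_baseline(c(corpus, one4)), uniform_baseline(corpus))
})

test_that("uniform weight tables spread parse mass uniformly", {
  # l = 4, single labels: 5 equiprobable topologies, 3 non-regular
  wt <- rule_weight_table(1, 1, 1, array(1, c(1, 1, 1)), matrix(1, 1, 1),
                          matrix(1, 4, 1))
  logZ <- inside_log_normalizer(wt)
  pl <- exp(topology_log_weight(wt, regular_tree(4, "LEFT")) - logZ)
  pr <- exp(topology_log_weight(wt, regular_tree(4, "RIGHT")) - logZ)
  expect_equal(pl, 0.2, tolerance = 1e-9)
  expect_equal(pr, 0.2, tolerance = 1e-9)
  expect_equal(1 - pl - pr, 0.6, tolerance = 1e-9)
})

test_that("rule frequencies are Dirichlet parameters minus base counts", {
  corpus <- toy_cluster_corpus(10, seed = 24)
  hy <- pcfg_hyperparams(K_beta = 2, K_gamma = 2)
  st <- init_pcfg_state(corpus, hy, seed = 1)
  # untrained state at exact base counts -> all frequencies zero
  bc <- pcfg_base_counts(hy, st$beta, st$gamma)
  st$dir_root <- bc$root
  st$dir_choice <- matrix(rep(bc$choice, each = 2), 2, 2)
  db <- array(0, c(2, 2, 2)); for (z in 1:2) db[z, , ] <- bc$branch
  st$dir_branch <- db
  st$dir_emit <- matrix(rep(bc$emit, each = 2), 2, 2)
  fr <- expected_rule_frequencies(st)
  for (f in fr) expect_true(all(f == 0))
  # after one e/m sweep, emission frequencies total the corpus length
  stats <- pcfg_e_step(st, corpus)
  st1 <- pcfg_m_step(st, stats)
  fr1 <- expected_rule_frequencies(st1)
  tot <- sum(vapply(corpus, nrow, 0L))
  # the stick update may shift bases slightly; clamped frequencies stay close
  expect_equal(sum(fr1$emit), tot, tolerance = 0.05 * tot)
  expect_true(all(unlist(fr1) >= 0))
})

test_that("step and tanh type counts match direct evaluation", {
  rc <- rule_type_counts(list(x = c(2.0, 0.5, 0.0)))
  expect_equal(rc$total_step, 1)
  expect_equal(rc$total_tanh, tanh(2) + tanh(0.5), tolerance = 1e-12)
  expect_equal(rc$total_tanh, 1.42614473733582, tolerance = 1e-10)
  z <- rule_type_counts(list(a = numeric(3), b = matrix(0, 2, 2)))
  expect_equal(z$total_step, 0)
  expect_equal(z$total_tanh, 0)
  # bounded by the positive support, monotone under increases
  f <- c(0.2, 1.5, 3, 0)
  rc2 <- rule_type_counts(list(f = f))
  expect_lte(rc2$total_step, sum(f > 0))
  expect_lte(rc2$total_tanh, sum(f > 0))
  rc3 <- rule_type_counts(list(f = f + 0.5))
  expect_gte(rc3$total_step, rc2$total_step)
  expect_gte(rc3$total_tanh, rc2$total_tanh)
})

test_that("comparison report lines up models computed on one corpus", {
  sf <- small_fit()
  hfit <- fit_hmm(sf$corpus, hmm_hyperparams(K_omega = 3),
                  fit_config(n_restarts = 1, tol = 0.2, max_iter = 30,
                             seed = 25))
  parse_rep <- expected_parse_counts(sf$fit, sf$corpus)
  pp <- predictive_report(sf$fit, sf$corpus)
  hh <- predictive_report(hfit, sf$corpus)
  # per-string values equal the predictive helper outputs
  expect_equal(pp$per_point[3],
               posterior_predictive_logdensity(sf$fit,
                                               sf$corpus[[3]])$per_point)
  expect_equal(hh$per_point[5],
               hmm_predictive_logdensity(hfit, sf$corpus[[5]])$per_point)
  out <- withr::local_tempdir()
  cmp <- compare_report(parse_rep, pp, hh,
                        rule_type_counts(expected_rule_frequencies(sf$fit)),
                        rule_type_counts(expected_rule_frequencies(hfit)),
                        out_dir = out)
  expect_true(file.exists(file.path(out, "comparison.json")))
  expect_true(file.exists(file.path(out, "predictive.csv")))
  expect_identical(cmp$predictive$model, c("PCFG", "HMM"))
  # mismatched corpora are refused
  hh_bad <- predictive_report(hfit, sf$corpus[1:5])
  expect_error(compare_report(parse_rep, pp, hh_bad,
                              rule_type_counts(list(a = 1)),
                              rule_type_counts(list(a = 1))),
               "different corpora")
})

test_that("identical corpora give zero predictive spread", {
  sf <- small_fit()
  same <- rep(sf$corpus[2], 6)
  pp <- predictive_report(sf$fit, same)
  expect_equal(pp$std, 0, tolerance = 1e-12)
  expect_equal(pp$mean, pp$per_point[1])
})

test_that("converted-HMM PCFG predictive equals the HMM forward predictive", {
  # likelihood-equality carried through the report layer
  set.seed(26)
  hp <- random_hmm_params(2)
  X <- matrix(stats::rnorm(10), 5, 2)
  q <- niw_params(c(0, 0), 3, diag(2), 4)
  ll <- cbind(niw_predictive_logdensity(q, X),
              niw_predictive_logdensity(niw_params(c(2, 2), 3, diag(2), 4),
                                        X))
  wt <- hmm_as_right_branching_pcfg(hp$init_p, hp$trans_p, hp$stop_p, ll)
  expect_equal(inside_log_normalizer(wt),
               hmm_forward_loglik(hp$init_p, hp$trans_p, hp$stop_p, ll),
               tolerance = 1e-9)
})
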