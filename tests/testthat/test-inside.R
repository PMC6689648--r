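# Weighted dynamic programming: inside totals, Viterbi, posterior and
# expected counts against brute-force enumeration oracles.

test_that("inside total of the all-ones table is the Catalan count", {
  for (l in 1:8) {
    wt <- rule_weight_table(1, 1, 1, array(1, c(1, 1, 1)), matrix(1, 1, 1),
                            matrix(1, l, 1))
    expect_equal(inside_log_normalizer(wt), log(count_parses(l)),
                 tolerance = 1e-12)
  }
})

test_that("l = 1 inside total is the single-rule product", {
  wt <- rule_weight_table(0.7, 0.2, 0.6, array(0.9, c(1, 1, 1)),
                          matrix(0.5, 1, 1), matrix(0.3, 1, 1))
  expect_equal(inside_log_normalizer(wt), log(0.7 * 0.6 * 0.5 * 0.3),
               tolerance = 1e-12)
})

test_that("inside and Viterbi agree with enumeration on random tables", {
  set.seed(101)
  for (rep in 1:60) {
    l <- sample(1:6, 1); K <- sample(1:3, 1); Kg <- sample(1:3, 1)
    wt <- random_weight_table(l, K, Kg)
    lo <- oracle_inside_logZ(wt)
    expect_equal(inside_log_normalizer(wt), lo,
                 tolerance = 1e-9 * max(1, abs(lo)))
    v <- viterbi_parse(wt)
    expect_equal(v$log_weight, oracle_viterbi_logw(wt), tolerance = 1e-9)
    expect_equal(tree_log_weight(wt, v$tree), v$log_weight,
                 tolerance = 1e-9)
    validate_tree(v$tree)
  }
})

test_that("compiled and reference kernels agree", {
  set.seed(202)
  for (rep in 1:20) {
    wt <- random_weight_table(sample(1:6, 1), sample(1:3, 1), sample(1:3, 1))
    a <- inside_outside_counts(wt)
    b <- inside_outside_counts_r(wt)
    for (f in c("log_Z", "root_counts", "branch_choice_counts",
                "emit_choice_counts", "branch_counts", "emit_counts", "resp"))
      expect_equal(a[[f]], b[[f]], tolerance = 1e-10)
    expect_equal(inside_log_normalizer(wt), inside_log_normalizer_r(wt),
                 tolerance = 1e-10)
  }
})

test_that("parse posteriors normalize and respect degenerate supports", {
  set.seed(33)
  # posteriors over all labeled parses sum to 1 (l <= 5)
  for (rep in 1:5) {
    l <- sample(2:5, 1); K <- 2; Kg <- 2
    wt <- random_weight_table(l, K, Kg)
    label_all <- function(topo) {
      rec <- function(nd) {
        if (nd$kind == "emit") {
          out <- list()
          for (z in 1:K) for (s in 1:Kg)
            out[[length(out) + 1]] <- emit_node(nd$pos, z = z, s = s)
          out
        } else {
          ls <- rec(nd$left); rs <- rec(nd$right); out <- list()
          for (z in 1:K) for (a in ls) for (b in rs)
            out[[length(out) + 1]] <- branch_node(a, b, z = z)
          out
        }
      }
      rec(topo)
    }
    tot <- 0
    for (tp in enumerate_topologies(l)) for (tr in label_all(tp))
      tot <- tot + parse_posterior(wt, tr)
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  # only right-branching rules weighted -> right tree posterior 1
  ll <- matrix(c(-40, -41), 4, 2, byrow = TRUE)
  hp <- random_hmm_params(2)
  wt <- hmm_as_right_branching_pcfg(hp$init_p, hp$trans_p, hp$stop_p, ll)
  v <- viterbi_parse(wt)
  expect_identical(classify_topology(v$tree), "RIGHT")
})

test_that("uniform weights resolve Viterbi ties to the right-branching chain", {
  wt <- rule_weight_table(c(1, 1), c(1, 1), c(1, 1), array(1, c(2, 2, 2)),
                          matrix(1, 2, 2), matrix(1, 5, 2))
  expect_identical(classify_topology(viterbi_parse(wt)$tree), "RIGHT")
})

test_that("inside total is monotone in every individual weight", {
  set.seed(44)
  wt <- random_weight_table(4, 2, 2)
  base <- inside_log_normalizer(wt)
  bump <- function(field, idx) {
    w2 <- unclass(wt)
    w2[[field]][idx] <- w2[[field]][idx] * 1.5
    rule_weight_table(w2$root_w, w2$branch_choice_w, w2$emit_choice_w,
                      w2$branch_w, w2$emit_w, w2$leaf_score)
  }
  for (field in c("root_w", "branch_choice_w", "emit_choice_w"))
    expect_gte(inside_log_normalizer(bump(field, 1)), base)
  expect_gte(inside_log_normalizer(bump("branch_w", 3)), base)
  expect_gte(inside_log_normalizer(bump("emit_w", 2)), base)
  expect_gte(inside_log_normalizer(bump("leaf_score", 5)), base)
})

test_that("expected counts match enumeration-weighted averages (l <= 4)", {
  set.seed(55)
  for (rep in 1:4) {
    l <- sample(2:4, 1); K <- 2; Kg <- 2
    wt <- random_weight_table(l, K, Kg)
    io <- inside_outside_counts(wt)
    # oracle: enumerate labeled parses, weight by exp(tree log weight)
    root_o <- numeric(K); branch_o <- array(0, c(K, K, K))
    emit_o <- matrix(0, K, Kg); wsum <- 0
    visit <- function(nd) {
      if (nd$kind == "emit") emit_cnt[nd$z, nd$s] <<- emit_cnt[nd$z, nd$s] + 1
      else {
        branch_cnt[nd$z, nd$left$z, nd$right$z] <<-
          branch_cnt[nd$z, nd$left$z, nd$right$z] + 1
        visit(nd$left); visit(nd$right)
      }
    }
    label_all <- function(topo) {
      rec <- function(nd) {
        if (nd$kind == "emit") {
          out <- list()
          for (z in 1:K) for (s in 1:Kg)
            out[[length(out) + 1]] <- emit_node(nd$pos, z = z, s = s)
          out
        } else {
          ls <- rec(nd$left); rs <- rec(nd$right); out <- list()
          for (z in 1:K) for (a in ls) for (b in rs)
            out[[length(out) + 1]] <- branch_node(a, b, z = z)
          out
        }
      }
      rec(topo)
    }
    for (tp in enumerate_topologies(l)) for (tr in label_all(tp)) {
      w <- exp(tree_log_weight(wt, tr))
      emit_cnt <- matrix(0, K, Kg); branch_cnt <- array(0, c(K, K, K))
      visit(tr)
      root_o[tr$z] <- root_o[tr$z] + w
      branch_o <- branch_o + w * branch_cnt
      emit_o <- emit_o + w * emit_cnt
      wsum <- wsum + w
    }
    expect_equal(io$root_counts, root_o / wsum, tolerance = 1e-9)
    expect_equal(io$branch_counts, branch_o / wsum, tolerance = 1e-9)
    expect_equal(io$emit_counts, emit_o / wsum, tolerance = 1e-9)
    expect_equal(rowSums(io$resp), rep(1, l), tolerance = 1e-9)
  }
})

test_that("zero-weight strings are reported, not crashed on", {
  wt <- rule_weight_table(1, 1, 1, array(1, c(1, 1, 1)), matrix(1, 1, 1),
                          matrix(0, 3, 1))
  expect_identical(inside_log_normalizer(wt), -Inf)
  expect_error(inside_outside_counts(wt), "total weight zero")
})
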