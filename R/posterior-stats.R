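# Posterior diagnostics: expected counts of parse categories, posterior
# predictive summaries, and expected rule-type counts (grammar compactness).

#' Expected counts of left-, right-branching and non-regular parses
#'
#' For every string of length >= 3, the posterior mass of the unique
#' left-branching and the unique right-branching topology (each summed over
#' all labelings by a constrained inside pass) is accumulated; non-regular
#' mass is the remainder. "Optimal" counts accumulate the posterior
#' probability of each string's Bayes-optimal (Viterbi) parse into its
#' topology class. Strings shorter than 3 have a unique parse that is both
#' regular topologies at once and are counted separately.
#'
#' @param state a fitted `pcfg_state`.
#' @param corpus list of feature strings or l x D matrices.
#' @return a `parse_count_report`: list with `totals` and `optimal` (named
#'   LEFT/RIGHT/NONREGULAR), `uniform_baseline`, `short_strings`, `N`,
#'   `N_l_ge_3`, `N_l_ge_4`, `pct_nonregular` (of all strings) and
#'   `pct_nonregular_l_ge_4`.
#' @export
expected_parse_counts <- function(state, corpus) {
  Xs <- as_feature_matrices(corpus)
  rw <- expected_log_weights(state)
  totals <- c(LEFT = 0, RIGHT = 0, NONREGULAR = 0)
  optimal <- c(LEFT = 0, RIGHT = 0, NONREGULAR = 0)
  short_strings <- 0L
  n_ge3 <- 0L; n_ge4 <- 0L
  for (X in Xs) {
    l <- nrow(X)
    if (l < 3) { short_strings <- short_strings + 1L; next }
    n_ge3 <- n_ge3 + 1L
    if (l >= 4) n_ge4 <- n_ge4 + 1L
    wt <- pcfg_string_table(state, X, rw)
    logZ <- inside_log_normalizer(wt)
    pl <- exp(topology_log_weight(wt, regular_tree(l, "LEFT")) - logZ)
    pr <- exp(topology_log_weight(wt, regular_tree(l, "RIGHT")) - logZ)
    totals["LEFT"] <- totals["LEFT"] + pl
    totals["RIGHT"] <- totals["RIGHT"] + pr
    totals["NONREGULAR"] <- totals["NONREGULAR"] + max(0, 1 - pl - pr)
    v <- viterbi_parse(wt)
    cls <- classify_topology(v$tree)
    optimal[cls] <- optimal[cls] + exp(v$log_weight - logZ)
  }
  structure(list(
    totals = totals, optimal = optimal,
    uniform_baseline = uniform_baseline(corpus),
    short_strings = short_strings,
    N = length(Xs), N_l_ge_3 = n_ge3, N_l_ge_4 = n_ge4,
    pct_nonregular = 100 * totals[["NONREGULAR"]] / length(Xs),
    pct_nonregular_l_ge_4 =
      if (n_ge4 > 0) 100 * totals[["NONREGULAR"]] / n_ge4 else NA_real_),
    class = "parse_count_report")
}

#' Expected count of a single parse under uniform parse distributions
#'
#' Sums, over strings of length >= 3, the probability any one parse would
#' receive if all binary topologies of the string were equiprobable -- the
#' reciprocal of the Catalan parse count.
#'
#' @param corpus list of feature strings or l x D matrices.
#' @return scalar expected count.
#' @export
uniform_baseline <- function(corpus) {
  ls <- vapply(as_feature_matrices(corpus), nrow, 0L)
  sum(vapply(ls[ls >= 3], function(l) 1 / count_parses(l), 0))
}

#' Per-point posterior predictive report
#'
#' Per-string per-data-point log posterior predictive density (log density
#' divided by string length), with mean and population standard deviation
#' over all strings and over the l >= 4 subgroup.
#'
#' @param state a fitted `pcfg_state` or `hmm_state`.
#' @param corpus list of feature strings or matrices.
#' @param method predictive estimator passed through (`"plugin"`, `"mc"`).
#' @return a `predictive_report`: list with `per_point` vector, `mean`,
#'   `std`, `mean_l_ge_4`, `std_l_ge_4`, `model`, `N`, `N_l_ge_4`.
#' @export
predictive_report <- function(state, corpus, method = "plugin") {
  Xs <- as_feature_matrices(corpus)
  fn <- if (inherits(state, "hmm_state")) hmm_predictive_logdensity
        else posterior_predictive_logdensity
  pp <- vapply(Xs, function(X) fn(state, X, method = method)$per_point, 0)
  ls <- vapply(Xs, nrow, 0L)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sub <- pp[ls >= 4]
  structure(list(
    per_point = pp, mean = mean(pp), std = pop_sd(pp),
    mean_l_ge_4 = if (length(sub)) mean(sub) else NA_real_,
    std_l_ge_4 = if (length(sub)) pop_sd(sub) else NA_real_,
    model = if (inherits(state, "hmm_state")) "HMM" else "PCFG",
    N = length(Xs), N_l_ge_4 = sum(ls >= 4)),
    class = "predictive_report")
}

#' Expected token frequencies of every rule
#'
#' The expected number of times each rule was used to generate the training
#' data: the rule's variational Dirichlet parameter minus its DP base count
#' (alpha_emit * gamma_s for emissions, alpha_branch * beta_B * beta_C for
#' branch pairs, alpha * beta_z or alpha * omega_k otherwise, 1 for the
#' Beta(1,1) choice factors). Tiny negatives from the degenerate-stick
#' update shifting the bases are clamped to zero.
#'
#' @param state a fitted `pcfg_state` or `hmm_state`.
#' @return named list of non-negative frequency arrays, one per rule class.
#' @export
expected_rule_frequencies <- function(state) {
  cl <- function(x) pmax(x, 0)
  if (inherits(state, "hmm_state")) {
    K <- state$hyper$K_omega
    base <- state$hyper$alpha * state$omega
    out <- list(initial = cl(state$dir_init - base),
                transition = cl(state$dir_trans -
                                  matrix(rep(base, each = K), K, K)))
    if (state$hyper$termination)
      out$stop <- cl(state$dir_stop - 1)
    return(out)
  }
  hyper <- state$hyper
  K <- hyper$K_beta
  bc <- pcfg_base_counts(hyper, state$beta, state$gamma)
  br <- state$dir_branch
  for (z in seq_len(K)) br[z, , ] <- br[z, , ] - bc$branch
  list(root = cl(state$dir_root - bc$root),
       choice = cl(state$dir_choice - 1),
       branch = cl(br),
       emit = cl(state$dir_emit -
                   matrix(rep(bc$emit, each = K), K, length(state$gamma))))
}

#' Occupied-component counts at an expected-frequency threshold
#'
#' Number of non-terminals/terminals (PCFG) or states (HMM) whose total
#' expected usage frequency exceeds the threshold (0.05 in the
#' truncation-adequacy convention).
#'
#' @param state a fitted `pcfg_state` or `hmm_state`.
#' @param threshold expected-frequency cutoff.
#' @return named integer vector.
#' @export
occupied_components <- function(state, threshold = 0.05) {
  fr <- expected_rule_frequencies(state)
  if (inherits(state, "hmm_state")) {
    usage <- fr$initial + colSums(fr$transition)
    return(c(states = sum(usage > threshold)))
  }
  K <- state$hyper$K_beta
  child_usage <- numeric(K)
  for (z in seq_len(K)) {
    m <- fr$branch[z, , ]
    child_usage <- child_usage + rowSums(m) + colSums(m)
  }
  c(nonterminals = sum(fr$root + child_usage > threshold),
    terminals = sum(colSums(fr$emit) > threshold))
}

#' Rule type counts under step and tanh activations
#'
#' Applies the step function `1[f >= 1]` and `tanh(f)` to the expected
#' token frequency of every rule and sums, per rule class and in total --
#' the compactness statistic.
#'
#' @param frequencies output of [expected_rule_frequencies()], or any named
#'   list of non-negative arrays.
#' @return a `rule_count_report`: list with `per_class` data.frame and
#'   `total_step`, `total_tanh`.
#' @export
rule_type_counts <- function(frequencies) {
  per <- data.frame(
    class = names(frequencies),
    step = vapply(frequencies, function(f) sum(f >= 1), 0),
    tanh = vapply(frequencies, function(f) sum(tanh(f)), 0),
    row.names = NULL)
  structure(list(per_class = per,
                 total_step = sum(per$step), total_tanh = sum(per$tanh)),
            class = "rule_count_report")
}

#' Side-by-side PCFG/HMM comparison report
#'
#' Combines parse-count, predictive and rule-count reports computed on the
#' same corpus into one structure (and optionally writes it as JSON plus
#' CSV tables).
#'
#' @param pcfg_parse a `parse_count_report`.
#' @param pcfg_pred,hmm_pred `predictive_report`s for the two models.
#' @param pcfg_rules,hmm_rules `rule_count_report`s for the two models.
#' @param out_dir optional directory to write `comparison.json`,
#'   `predictive.csv` and `rule_counts.csv` into.
#' @return a `comparison_report` list.
#' @export
compare_report <- function(pcfg_parse, pcfg_pred, hmm_pred,
                           pcfg_rules, hmm_rules, out_dir = NULL) {
  if (pcfg_pred$N != hmm_pred$N)
    stop("PCFG and HMM reports were computed on different corpora")
  predictive <- data.frame(
    model = c(pcfg_pred$model, hmm_pred$model),
    mean = c(pcfg_pred$mean, hmm_pred$mean),
    std = c(pcfg_pred$std, hmm_pred$std),
    mean_l_ge_4 = c(pcfg_pred$mean_l_ge_4, hmm_pred$mean_l_ge_4),
    std_l_ge_4 = c(pcfg_pred$std_l_ge_4, hmm_pred$std_l_ge_4))
  rules <- data.frame(
    model = c("PCFG", "HMM"),
    step = c(pcfg_rules$total_step, hmm_rules$total_step),
    tanh = c(pcfg_rules$total_tanh, hmm_rules$total_tanh))
  rep <- structure(list(parse_counts = pcfg_parse, predictive = predictive,
                        rule_type_counts = rules),
                   class = "comparison_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(parse_counts = unclass(pcfg_parse), predictive = predictive,
           rule_type_counts = rules),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(predictive, file.path(out_dir, "predictive.csv"),
                     row.names = FALSE)
    utils::write.csv(rules, file.path(out_dir, "rule_counts.csv"),
                     row.names = FALSE)
  }
  rep
}
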