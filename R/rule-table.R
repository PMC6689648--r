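# Weighted dynamic programming over binary-branching grammars.
#
# A RuleWeightTable holds arbitrary non-negative weights (in inference these
# are exp of expected log probabilities, so they need not normalize):
#   root_w[z]          weight of z labelling the root
#   branch_choice_w[z] weight of z choosing to branch
#   emit_choice_w[z]   weight of z choosing to emit
#   branch_w[z,y1,y2]  weight of the rewrite z -> y1 y2
#   emit_w[z,s]        weight of z emitting terminal s
#   leaf_score[i,s]    per-position density score of terminal s (data term)
#
# Charts use half-open spans [i, j) over 1-based positions; the leaf at
# position i is span [i, i+1). Computations run in linear space with
# per-position rescaling of the leaf scores (their magnitudes carry the
# Gaussian densities), and log space for Viterbi.

#' Construct a rule weight table
#'
#' @param root_w length-K non-negative vector.
#' @param branch_choice_w,emit_choice_w length-K non-negative vectors.
#' @param branch_w K x K x K non-negative array indexed `[z, y1, y2]`.
#' @param emit_w K x Kg non-negative matrix.
#' @param leaf_score l x Kg non-negative matrix of per-position terminal
#'   scores (density values).
#' @param leaf_log_shift optional length-l vector of per-position log scale
#'   factors: the effective leaf score is `leaf_score[i, s] *
#'   exp(leaf_log_shift[i])`. Lets callers pass heavily underflowing
#'   densities (e.g. 13-dim Gaussian scores) without loss.
#' @return an object of class `rule_weight_table`.
#' @export
rule_weight_table <- function(root_w, branch_choice_w, emit_choice_w,
                              branch_w, emit_w, leaf_score,
                              leaf_log_shift = NULL) {
  K <- length(root_w)
  leaf_score <- as.matrix(leaf_score)
  emit_w <- as.matrix(emit_w)
  Kg <- ncol(emit_w)
  if (length(branch_choice_w) != K || length(emit_choice_w) != K)
    stop("choice weight vectors must have length K")
  if (!identical(dim(branch_w), c(K, K, K)))
    stop("`branch_w` must be a K x K x K array")
  if (nrow(emit_w) != K) stop("`emit_w` must be K x Kg")
  if (ncol(leaf_score) != Kg) stop("`leaf_score` must be l x Kg")
  ws <- c(root_w, branch_choice_w, emit_choice_w, branch_w, emit_w, leaf_score)
  if (any(!is.finite(ws)) || any(ws < 0))
    stop("all weights must be finite and non-negative")
  leaf_log_shift <- leaf_log_shift %||% numeric(nrow(leaf_score))
  if (length(leaf_log_shift) != nrow(leaf_score))
    stop("`leaf_log_shift` must have one entry per position")
  structure(list(root_w = as.numeric(root_w),
                 branch_choice_w = as.numeric(branch_choice_w),
                 emit_choice_w = as.numeric(emit_choice_w),
                 branch_w = branch_w, emit_w = emit_w,
                 leaf_score = leaf_score,
                 leaf_log_shift = as.numeric(leaf_log_shift),
                 K = K, Kg = Kg, l = nrow(leaf_score)),
            class = "rule_weight_table")
}

# Scaled inside chart. Every parse of a length-l string has exactly l - 1
# branch nodes and l emit nodes, so the per-node-type weight products
# (branch_choice * branch rule, emit_choice * emit rule) can be normalized
# by their maxima with the log factors carried exactly -- this keeps the
# chart in a safe floating-point range even when exp(E[log phi]) weights
# are astronomically small (large truncations, long strings).
# Returns Ihat[l+1, l+1, K], the normalized node matrices and the total
# log scale; Zhat is the scaled inside total.
inside_chart <- function(wt) {
  l <- wt$l; K <- wt$K
  cs <- apply(wt$leaf_score, 1, max)
  if (any(cs <= 0)) return(list(Zhat = 0, logscale = -Inf, Ihat = NULL))
  leafhat <- wt$leaf_score / cs
  Bn <- wt$branch_choice_w *
    matrix(wt$branch_w, K, K * K) # column index = y1 + (y2-1)*K
  En <- wt$emit_choice_w * wt$emit_w
  cE <- max(En)
  if (cE <= 0) return(list(Zhat = 0, logscale = -Inf, Ihat = NULL))
  En <- En / cE
  logscale <- sum(log(cs)) + l * log(cE)
  cB <- max(Bn)
  if (l >= 2) {
    if (cB <= 0) return(list(Zhat = 0, logscale = -Inf, Ihat = NULL))
    Bn <- Bn / cB
    logscale <- logscale + (l - 1) * log(cB)
  }
  Ihat <- array(0, dim = c(l + 1, l + 1, K))
  for (i in seq_len(l))
    Ihat[i, i + 1, ] <- as.vector(En %*% leafhat[i, ])
  if (l >= 2) {
    for (w in 2:l) {
      for (i in seq_len(l - w + 1)) {
        j <- i + w
        u <- numeric(K * K)
        for (k in (i + 1):(j - 1))
          u <- u + as.vector(outer(Ihat[i, k, ], Ihat[k, j, ]))
        Ihat[i, j, ] <- as.vector(Bn %*% u)
      }
    }
  }
  list(Zhat = sum(wt$root_w * Ihat[1, l + 1, ]), logscale = logscale,
       Ihat = Ihat, leafhat = leafhat, Bn = Bn, En = En)
}

#' Log total weight of all labeled parses of a string
#'
#' CYK-style inside pass: `log` of the sum, over every labeled binary parse,
#' of the product of rule weights along the tree times the leaf scores.
#'
#' @param wt a [rule_weight_table()] (its `leaf_score` fixes the string
#'   length).
#' @return scalar log normalizer; `-Inf` when no parse has positive weight.
#' @export
inside_log_normalizer <- function(wt) {
  lz <- .inside_logZ_cpp(wt$root_w, wt$branch_choice_w, wt$emit_choice_w,
                         matrix(wt$branch_w, wt$K, wt$K * wt$K), wt$emit_w,
                         wt$leaf_score)
  if (!is.finite(lz)) return(-Inf)
  lz + sum(wt$leaf_log_shift)
}

#' @rdname inside_log_normalizer
#' @details `inside_log_normalizer_r()` is the pure-R reference
#'   implementation of the same chart, kept as an independent cross-check of
#'   the compiled kernel.
#' @export
inside_log_normalizer_r <- function(wt) {
  ch <- inside_chart(wt)
  if (ch$Zhat <= 0) return(-Inf)
  log(ch$Zhat) + ch$logscale + sum(wt$leaf_log_shift)
}

#' Log weight of one fully labeled parse tree
#'
#' @param wt a [rule_weight_table()].
#' @param tree a parse tree with all `z` and `s` labels set.
#' @return scalar log weight (`-Inf` if any factor is zero).
#' @export
tree_log_weight <- function(wt, tree) {
  rec <- function(nd) {
    if (nd$kind == "emit")
      log(wt$emit_choice_w[nd$z]) + log(wt$emit_w[nd$z, nd$s]) +
        log(wt$leaf_score[nd$pos, nd$s])
    else
      log(wt$branch_choice_w[nd$z]) +
        log(wt$branch_w[nd$z, nd$left$z, nd$right$z]) +
        rec(nd$left) + rec(nd$right)
  }
  log(wt$root_w[tree$z]) + rec(tree) + sum(wt$leaf_log_shift)
}

#' Log weight of a topology, summed over all labelings
#'
#' Marginalizes the non-terminal and terminal labels of a fixed topology by
#' recursive sum-product over the tree (an inside pass constrained to that
#' topology). Used for the left/right-branching parse totals and as a
#' building block of enumeration oracles.
#'
#' @param wt a [rule_weight_table()].
#' @param topo an (unlabeled) parse tree whose leaves cover the string.
#' @return scalar log of the summed weight.
#' @export
topology_log_weight <- function(wt, topo) {
  K <- wt$K
  rec <- function(nd) { # returns K-vector of log subtree weights given label
    if (nd$kind == "emit") {
      lv <- log(wt$emit_w %*% wt$leaf_score[nd$pos, ])
      log(wt$emit_choice_w) + as.vector(lv)
    } else {
      ml <- rec(nd$left); mr <- rec(nd$right)
      mx <- max(ml) + max(mr)
      if (!is.finite(mx)) return(rep(-Inf, K))
      w <- exp(ml - max(ml)) %o% exp(mr - max(mr)) # [y1, y2]
      tot <- apply(wt$branch_w, 1, function(bz) sum(matrix(bz, K, K) * w))
      log(wt$branch_choice_w) + log(tot) + mx
    }
  }
  logsumexp(log(wt$root_w) + rec(topo)) + sum(wt$leaf_log_shift)
}

#' Posterior probability of one labeled parse under a weight table
#'
#' @param wt a [rule_weight_table()].
#' @param tree a fully labeled parse tree.
#' @return `exp(tree_log_weight - inside_log_normalizer)`, in \[0, 1\].
#' @export
parse_posterior <- function(wt, tree) {
  exp(tree_log_weight(wt, tree) - inside_log_normalizer(wt))
}

#' Maximum-weight labeled parse (Viterbi)
#'
#' Log-space CYK max chart with deterministic tie-breaking: on exact ties the
#' smallest split point wins (so uniform weights yield the right-branching
#' chain), then the smallest label indices.
#'
#' @param wt a [rule_weight_table()].
#' @return list with `tree` (fully labeled) and `log_weight`.
#' @export
viterbi_parse <- function(wt) {
  l <- wt$l; K <- wt$K
  lw <- list(root = log(wt$root_w), bc = log(wt$branch_choice_w),
             ec = log(wt$emit_choice_w), B = log(wt$branch_w),
             E = log(wt$emit_w), L = log(wt$leaf_score))
  V <- array(-Inf, dim = c(l + 1, l + 1, K))
  bp <- vector("list", (l + 1)^2 * K)
  dim(bp) <- c(l + 1, l + 1, K)
  for (i in seq_len(l)) {
    sc <- sweep(lw$E, 2, lw$L[i, ], `+`) # [z, s]
    s_best <- apply(sc, 1, which.max)
    V[i, i + 1, ] <- lw$ec + sc[cbind(seq_len(K), s_best)]
    for (z in seq_len(K)) bp[[i, i + 1, z]] <- list(s = s_best[z])
  }
  if (l >= 2) {
    for (w in 2:l) for (i in seq_len(l - w + 1)) {
      j <- i + w
      best <- rep(-Inf, K); arg <- vector("list", K)
      for (k in (i + 1):(j - 1)) {
        m <- outer(V[i, k, ], V[k, j, ], `+`) # [y1, y2]
        for (z in seq_len(K)) {
          cand <- lw$B[z, , ] + m
          ix <- which.max(cand) # column-major: earliest y1 then y2 on ties
          if (cand[ix] > best[z]) {
            best[z] <- cand[ix]
            arg[[z]] <- list(k = k, y1 = (ix - 1) %% K + 1,
                             y2 = (ix - 1) %/% K + 1)
          }
        }
      }
      V[i, j, ] <- lw$bc + best
      for (z in seq_len(K))
        if (!is.null(arg[[z]])) bp[[i, j, z]] <- arg[[z]]
    }
  }
  rootsc <- lw$root + V[1, l + 1, ]
  r <- which.max(rootsc)
  build <- function(i, j, z) {
    a <- bp[[i, j, z]]
    if (j - i == 1L) emit_node(i, z = z, s = a$s)
    else branch_node(build(i, a$k, a$y1), build(a$k, j, a$y2), z = z)
  }
  list(tree = build(1L, l + 1L, r),
       log_weight = rootsc[r] + sum(wt$leaf_log_shift))
}

#' Inside-outside expected rule counts for one string
#'
#' Runs scaled inside and outside passes and returns the expected counts of
#' every rule occurrence under the parse distribution proportional to the
#' table's weights, plus per-position terminal responsibilities.
#'
#' @param wt a [rule_weight_table()].
#' @return list with `log_Z`, `root_counts` (K), `branch_choice_counts` (K),
#'   `emit_choice_counts` (K), `branch_counts` (K x K x K),
#'   `emit_counts` (K x Kg), `resp` (l x Kg; rows sum to 1).
#' @export
inside_outside_counts <- function(wt) {
  io <- .inside_outside_cpp(wt$root_w, wt$branch_choice_w, wt$emit_choice_w,
                            matrix(wt$branch_w, wt$K, wt$K * wt$K),
                            wt$emit_w, wt$leaf_score)
  list(log_Z = io$log_Z + sum(wt$leaf_log_shift),
       root_counts = as.vector(io$root_counts),
       branch_choice_counts = as.vector(io$branch_choice_counts),
       emit_choice_counts = rowSums(io$emit_counts),
       branch_counts = array(io$branch_counts, dim = c(wt$K, wt$K, wt$K)),
       emit_counts = io$emit_counts,
       resp = io$resp / rowSums(io$resp))
}

#' @rdname inside_outside_counts
#' @details `inside_outside_counts_r()` is the pure-R reference
#'   implementation, retained as an independent cross-check of the compiled
#'   kernel.
#' @export
inside_outside_counts_r <- function(wt) {
  l <- wt$l; K <- wt$K; Kg <- wt$Kg
  ch <- inside_chart(wt)
  if (is.null(ch$Ihat) || ch$Zhat <= 0)
    stop("string has total weight zero (no parse with positive weight)")
  Ihat <- ch$Ihat; Zhat <- ch$Zhat; Bn <- ch$Bn; En <- ch$En
  Ohat <- array(0, dim = c(l + 1, l + 1, K))
  Ohat[1, l + 1, ] <- wt$root_w
  branch_counts_m <- matrix(0, K, K * K)
  branch_choice_counts <- numeric(K)
  if (l >= 2) {
    for (w in l:2) for (i in seq_len(l - w + 1)) {
      j <- i + w
      oz <- Ohat[i, j, ]
      branch_choice_counts <- branch_choice_counts + oz * Ihat[i, j, ]
      W <- matrix(as.vector(crossprod(Bn, oz)), K, K) # [y1, y2]
      for (k in (i + 1):(j - 1)) {
        u <- as.vector(outer(Ihat[i, k, ], Ihat[k, j, ]))
        branch_counts_m <- branch_counts_m + (oz %o% u) * Bn
        Ohat[i, k, ] <- Ohat[i, k, ] + as.vector(W %*% Ihat[k, j, ])
        Ohat[k, j, ] <- Ohat[k, j, ] + as.vector(crossprod(W, Ihat[i, k, ]))
      }
    }
  }
  emit_counts <- matrix(0, K, Kg)
  resp <- matrix(0, l, Kg)
  for (i in seq_len(l)) {
    m <- (Ohat[i, i + 1, ] %o% ch$leafhat[i, ]) * En / Zhat
    emit_counts <- emit_counts + m
    resp[i, ] <- colSums(m)
  }
  # the emit-choice mass of z is the total posterior mass of leaves labeled z
  emit_choice_counts <- rowSums(emit_counts)
  list(log_Z = log(Zhat) + ch$logscale + sum(wt$leaf_log_shift),
       root_counts = wt$root_w * Ihat[1, l + 1, ] / Zhat,
       branch_choice_counts = branch_choice_counts / Zhat,
       emit_choice_counts = emit_choice_counts,
       branch_counts = array(branch_counts_m / Zhat, dim = c(K, K, K)),
       emit_counts = emit_counts,
       resp = resp)
}
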