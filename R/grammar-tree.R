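# Parse trees for binary-branching grammars with terminal emissions.
#
# A tree node is a plain list. Every node carries a non-terminal label `z`
# (NA in unlabeled topologies) and a choice indicator `kind`:
#   - kind = "emit":   the non-terminal emits terminal `s` at string
#                      position `pos` (1-based).
#   - kind = "branch": the non-terminal rewrites into `left` and `right`.
# The root's `z` is the (variable) root label of the parse. Leaves of the
# binary topology are exactly the emit nodes, so a string of length l has
# l emit nodes and l - 1 branch nodes.

#' Create an emitting (leaf) parse-tree node
#' @param pos 1-based string position covered by this node.
#' @param z non-terminal label (integer) or `NA` for a bare topology.
#' @param s terminal label (integer) or `NA`.
#' @return a parse-tree node.
#' @export
emit_node <- function(pos, z = NA_integer_, s = NA_integer_) {
  list(kind = "emit", z = z, s = s, pos = pos)
}

#' Create a branching parse-tree node
#' @param left,right child nodes.
#' @param z non-terminal label (integer) or `NA`.
#' @return a parse-tree node.
#' @export
branch_node <- function(left, right, z = NA_integer_) {
  list(kind = "branch", z = z, left = left, right = right)
}

#' String length covered by a parse tree
#' @param tree a parse tree.
#' @return integer number of emit nodes (leaves).
#' @export
tree_length <- function(tree) {
  if (tree$kind == "emit") 1L
  else tree_length(tree$left) + tree_length(tree$right)
}

#' Positions of the leaves, left to right
#' @keywords internal
tree_positions <- function(tree) {
  if (tree$kind == "emit") tree$pos
  else c(tree_positions(tree$left), tree_positions(tree$right))
}

#' Validate a parse tree over positions 1..l
#' @param tree a parse tree.
#' @return invisibly `TRUE`; stops on malformed trees.
#' @export
validate_tree <- function(tree) {
  pos <- tree_positions(tree)
  if (!identical(as.integer(pos), seq_len(length(pos))))
    stop("leaves must cover positions 1..l exactly once, in order")
  invisible(TRUE)
}

#' Number of binary parse topologies of a string
#'
#' A string of length `l` has Catalan(l - 1) distinct binary-branching
#' topologies: C_n = choose(2n, n) / (n + 1).
#'
#' @param l string length (>= 1).
#' @return exact integer-valued count.
#' @export
#' @examples
#' count_parses(4) # 5
count_parses <- function(l) {
  if (!is.numeric(l) || length(l) != 1L || l < 1 || l != round(l))
    stop("`l` must be a positive integer")
  n <- l - 1
  round(choose(2 * n, n) / (n + 1))
}

#' Enumerate all binary parse topologies of a string
#'
#' Exhaustive construction used as a brute-force oracle; guarded against
#' combinatorial explosion.
#'
#' @param l string length (1 <= l <= 12).
#' @return list of unlabeled parse trees (`z`, `s` set to `NA`).
#' @export
enumerate_topologies <- function(l) {
  if (l < 1) stop("`l` must be >= 1")
  if (l > 12) stop("refusing to enumerate topologies for l > 12")
  rec <- function(i, j) { # half-open span [i, j), 1-based positions
    if (j - i == 1L) return(list(emit_node(i)))
    out <- list()
    for (k in (i + 1L):(j - 1L)) {
      for (lt in rec(i, k)) for (rt in rec(k, j))
        out[[length(out) + 1L]] <- branch_node(lt, rt)
    }
    out
  }
  rec(1L, l + 1L)
}

#' Classify a parse topology as left-branching, right-branching or neither
#'
#' Left-branching (regular): every branch node's right child is a leaf.
#' Right-branching (regular): every branch node's left child is a leaf.
#' Strings shorter than 3 have a unique parse that is both; non-regular
#' topologies first appear at l = 4.
#'
#' @param tree a parse tree.
#' @return one of `"LEFT"`, `"RIGHT"`, `"BOTH_REGULAR"`, `"NONREGULAR"`.
#' @export
classify_topology <- function(tree) {
  l <- tree_length(tree)
  if (l <= 2) return("BOTH_REGULAR")
  all_left <- function(nd) nd$kind == "emit" ||
    (nd$right$kind == "emit" && all_left(nd$left))
  all_right <- function(nd) nd$kind == "emit" ||
    (nd$left$kind == "emit" && all_right(nd$right))
  if (all_left(tree)) "LEFT" else if (all_right(tree)) "RIGHT" else "NONREGULAR"
}

#' The unique fully left- or right-branching topology
#' @param l string length (>= 1).
#' @param side `"LEFT"` or `"RIGHT"`.
#' @return an unlabeled parse tree.
#' @export
regular_tree <- function(l, side = c("RIGHT", "LEFT")) {
  side <- match.arg(side)
  if (l < 1) stop("`l` must be >= 1")
  if (l == 1) return(emit_node(1L))
  if (side == "RIGHT") {
    t <- emit_node(as.integer(l))
    for (i in rev(seq_len(l - 1))) t <- branch_node(emit_node(as.integer(i)), t)
  } else {
    t <- emit_node(1L)
    for (i in 2:l) t <- branch_node(t, emit_node(as.integer(i)))
  }
  t
}

#' Serialize a parse tree to a bracketed string
#'
#' Branch nodes render as `(z left right)`, emit nodes as `(z s<k>)` with
#' integer labels; `NA` labels render as `_`.
#'
#' @param tree a parse tree.
#' @return a single string, e.g. `"(3 (1 s4) (2 (0 s7) (0 s2)))"`.
#' @export
tree_to_bracket <- function(tree) {
  lab <- function(z) if (is.na(z)) "_" else as.character(z)
  if (tree$kind == "emit")
    sprintf("(%s s%s)", lab(tree$z), if (is.na(tree$s)) "_" else tree$s)
  else
    sprintf("(%s %s %s)", lab(tree$z),
            tree_to_bracket(tree$left), tree_to_bracket(tree$right))
}

#' Parse a bracketed string back into a parse tree
#' @param x a string produced by [tree_to_bracket()].
#' @return a parse tree with leaf positions assigned left to right.
#' @export
bracket_to_tree <- function(x) {
  toks <- regmatches(x, gregexpr("\\(|\\)|[^()[:space:]]+", x))[[1]]
  i <- 0L; pos <- 0L
  nxt <- function() {
    i <<- i + 1L
    if (i > length(toks)) stop("malformed bracket string (truncated)")
    toks[i]
  }
  lab <- function(tok) if (tok == "_") NA_integer_ else as.integer(tok)
  rec <- function() {
    if (nxt() != "(") stop("malformed bracket string")
    z <- lab(nxt())
    tok <- nxt()
    if (grepl("^s", tok)) { # emit node
      pos <<- pos + 1L
      node <- emit_node(pos, z = z, s = lab(sub("^s", "", tok)))
      if (nxt() != ")") stop("malformed bracket string")
      return(node)
    }
    i <<- i - 1L
    left <- rec(); right <- rec()
    if (nxt() != ")") stop("malformed bracket string")
    branch_node(left, right, z = z)
  }
  out <- rec()
  if (i != length(toks)) stop("trailing tokens in bracket string")
  out
}
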