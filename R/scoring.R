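## Closed-form MR supertree distances via the relationship matrix:
##   d-  = 2C (+ m for multifurcating input trees)
##   d+g = B + C       (computed on the dummy-modified supertree)
##   d+  = 2B          (computed on the dummy-modified supertree)
## where C counts input-tree splits incompatible with >= 1 supertree split
## and B counts supertree splits incompatible with >= 1 input-tree split.

DUMMY_PREFIX <- "__mrst_dummy_"

#' Supported supertree methods
#'
#' `"minus"` = MR(-): RF between the pruned supertree and each input;
#' `"plus"` = MR(+): RF to the best bifurcating edge-only extension of each
#' input; `"plusg"` = MR(+)g: RF to the best edge-or-node extension.
#'
#' @param method a method string.
#' @return the matched method string.
#' @export
mr_method <- function(method = c("minus", "plus", "plusg")) {
  match.arg(method)
}

#' Collapse supertree subtrees containing no input-tree taxa
#'
#' Every maximal subtree of `S` hanging off a single edge and containing
#' only taxa absent from `input_taxa` is replaced by a fresh dummy taxon.
#' This is the modification under which the closed-form score formulas are
#' stated: each dummy stands for a whole subtree that can be grafted onto
#' an extended input tree at no cost.
#'
#' @param S a bifurcating `mr_tree`.
#' @param input_taxa character vector of the input tree's taxa.
#' @return an `mr_tree` (bifurcating, possibly with dummy taxa named with a
#'   reserved prefix).
#' @export
modify_supertree <- function(S, input_taxa) {
  T0 <- S$taxa[S$taxa %in% input_taxa]
  if (length(T0) < 3L) stop("fewer than 3 shared taxa")
  if (any(startsWith(S$taxa, DUMMY_PREFIX)))
    stop("supertree already contains reserved dummy labels")
  ## all split sides empty of input taxa
  sides <- list()
  for (s in S$splits) {
    if (!any(s$left %in% T0)) sides <- c(sides, list(s$left))
    if (!any(s$right %in% T0)) sides <- c(sides, list(s$right))
  }
  if (length(sides) == 0L) return(S)
  ## keep maximal sides only (sides are nested or disjoint)
  ord <- order(vapply(sides, length, integer(1)), decreasing = TRUE)
  sides <- sides[ord]
  maximal <- list()
  for (x in sides) {
    contained <- any(vapply(maximal, function(m) all(x %in% m), logical(1)))
    if (!contained) maximal <- c(maximal, list(x))
  }
  dummies <- paste0(DUMMY_PREFIX, seq_along(maximal))
  collapsed <- unlist(maximal)
  newsp <- list()
  for (s in S$splits) {
    drop <- FALSE
    for (m in maximal) {
      if (all(s$left %in% m) || all(s$right %in% m)) { drop <- TRUE; break }
    }
    if (drop) next
    l <- s$left; r <- s$right
    for (k in seq_along(maximal)) {
      m <- maximal[[k]]
      if (all(m %in% l)) l <- c(setdiff(l, m), dummies[k])
      else if (all(m %in% r)) r <- c(setdiff(r, m), dummies[k])
    }
    newsp[[length(newsp) + 1L]] <- new_split(sort(l), sort(r))
  }
  mr_tree(c(setdiff(S$taxa, collapsed), dummies), newsp, validate = FALSE)
}

#' Build the relationship matrix of an input tree and a supertree
#'
#' For every (input split, supertree split) pair the entry is `"s"`
#' (subsplit), `"i"` (incompatible after restriction to the shared taxa) or
#' `"c"` (compatible but no subsplit).  Indicator vectors `c_i` (row has at
#' least one `"i"`) and `b_j` (column has at least one `"i"`) are attached.
#' Trivial splits can never be incompatible, so including them (as the
#' constructive proofs do for subsplit bookkeeping) changes neither `C` nor
#' `B`.
#'
#' @param G the input tree (`mr_tree`).
#' @param S_mod the (typically dummy-modified) supertree.
#' @param include_trivial also include the terminal splits of `G` and the
#'   terminal splits of `S_mod` for taxa shared with `G` (used by the
#'   witness construction).
#' @return an object of class `mr_relmat`: a character matrix with
#'   attributes `c`, `b`, `row_splits`, `col_splits`.
#' @export
build_relationship_matrix <- function(G, S_mod, include_trivial = FALSE) {
  gs <- G$splits
  ss <- S_mod$splits
  if (include_trivial) {
    gs <- tree_splits(G, trivial = TRUE)
    shared <- S_mod$taxa[S_mod$taxa %in% G$taxa]
    ss <- c(ss, lapply(shared, function(x)
      new_split(x, setdiff(S_mod$taxa, x))))
  }
  m <- matrix("c", nrow = length(gs), ncol = length(ss),
              dimnames = list(paste0("g", seq_along(gs)),
                              paste0("s", seq_along(ss))))
  for (i in seq_along(gs)) for (j in seq_along(ss)) {
    if (is_subsplit(gs[[i]], ss[[j]])) m[i, j] <- "s"
    else if (!are_compatible(gs[[i]], ss[[j]])) m[i, j] <- "i"
  }
  ci <- as.integer(apply(m == "i", 1L, any))
  bj <- as.integer(apply(m == "i", 2L, any))
  if (length(gs) == 0L) { ci <- integer(0) }
  if (length(ss) == 0L) { bj <- integer(0) }
  structure(m, c = ci, b = bj, row_splits = gs, col_splits = ss,
            class = c("mr_relmat", class(m)))
}

#' @export
print.mr_relmat <- function(x, ...) {
  m <- cbind(unclass(x), c_i = attr(x, "c"))
  print(m, quote = FALSE)
  cat("b_j:", paste(attr(x, "b"), collapse = " "), "\n")
  invisible(x)
}

#' Conflict counts of a relationship matrix
#'
#' @param M an `mr_relmat`.
#' @return named integer vector `c(C = sum(c_i), B = sum(b_j))`.
#' @export
conflict_counts <- function(M) {
  c(C = sum(attr(M, "c")), B = sum(attr(M, "b")))
}

check_pair <- function(S, G, need_bif_G = TRUE) {
  if (!is_bifurcating(S)) stop("the supertree must be bifurcating")
  if (need_bif_G && !is_bifurcating(G)) stop("the input tree must be bifurcating")
  shared <- S$taxa[S$taxa %in% G$taxa]
  if (length(shared) < 3L) stop("fewer than 3 shared taxa")
  shared
}

#' MR(-) distance
#'
#' `2C + m`, where `C` is the number of inner splits of `G` incompatible
#' with at least one split of `S` and `m` is the multifurcation count of
#' `G`.  Equals the RF distance between the supertree pruned to the input
#' taxa and the input tree.
#'
#' @param S bifurcating supertree (`mr_tree`).
#' @param G input tree (multifurcations allowed).
#' @return non-negative integer.
#' @export
d_minus <- function(S, G) {
  shared <- check_pair(S, G, need_bif_G = FALSE)
  if (!all(G$taxa %in% S$taxa)) G <- restrict_tree(G, shared)
  C <- sum(vapply(G$splits, function(g)
    any(vapply(S$splits, function(s) !are_compatible(g, s), logical(1))),
    logical(1)))
  2L * C + multifurcations(G)
}

#' MR(+)g distance
#'
#' `B + C` computed on the dummy-modified supertree: the minimum RF over
#' all extensions of `G` placing the missing taxa onto edges or nodes.
#'
#' @param S,G bifurcating `mr_tree` objects.
#' @return non-negative integer.
#' @export
d_plus_g <- function(S, G) {
  check_pair(S, G)
  if (!all(G$taxa %in% S$taxa)) G <- restrict_tree(G, S$taxa)
  Sm <- modify_supertree(S, G$taxa)
  cc <- conflict_counts(build_relationship_matrix(G, Sm))
  unname(cc["B"] + cc["C"])
}

#' MR(+) distance
#'
#' `2B` computed on the dummy-modified supertree: the minimum RF over all
#' bifurcating edge-only extensions of `G`.
#'
#' @param S,G bifurcating `mr_tree` objects.
#' @return non-negative integer.
#' @export
d_plus <- function(S, G) {
  check_pair(S, G)
  if (!all(G$taxa %in% S$taxa)) G <- restrict_tree(G, S$taxa)
  Sm <- modify_supertree(S, G$taxa)
  cc <- conflict_counts(build_relationship_matrix(G, Sm))
  unname(2L * cc["B"])
}

#' Total score of a supertree against a set of input trees
#'
#' The sum of the per-input-tree distance of the chosen method.  Inputs
#' sharing fewer than 3 taxa with the supertree contribute 0, with a
#' warning (there is no check for sufficient overlap beyond this).
#'
#' @param S supertree spanning the union of input taxa.
#' @param inputs list of `mr_tree`.
#' @param method see [mr_method()].
#' @return non-negative integer.
#' @export
total_score <- function(S, inputs, method = c("minus", "plus", "plusg")) {
  method <- mr_method(method)
  f <- switch(method, minus = d_minus, plus = d_plus, plusg = d_plus_g)
  tot <- 0L
  for (G in inputs) {
    if (!all(G$taxa %in% S$taxa))
      stop("supertree is missing taxa present in an input tree")
    shared <- S$taxa[S$taxa %in% G$taxa]
    if (length(shared) < 3L) {
      warning("input tree shares fewer than 3 taxa with the supertree; ",
              "it contributes 0 to the score")
      next
    }
    tot <- tot + f(S, G)
  }
  tot
}
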