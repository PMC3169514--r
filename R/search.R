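## Heuristic minimization over bifurcating supertrees: step-wise addition
## starting tree, NNI local moves, TDR restarts, and the two-stage
## exploration/broadening schedule.  The hot path runs in C++ over bitmask
## splits; this file owns validation, conversion and the result contract.

method_code <- function(method) {
  switch(mr_method(method), minus = 0L, plus = 1L, plusg = 2L)
}

taxon_union <- function(inputs) {
  sort(unique(unlist(lapply(inputs, function(t) t$taxa))))
}

## convert trees to the 0-based index representation of the C++ core
as_cpp_inputs <- function(inputs, universe) {
  if (length(universe) > 128L)
    stop("the search core supports at most 128 taxa")
  lapply(inputs, function(t) {
    list(taxa = match(t$taxa, universe) - 1L,
         splits = lapply(t$splits, function(s) match(s$left, universe) - 1L))
  })
}

as_cpp_tree <- function(t, universe) {
  list(taxa = match(t$taxa, universe) - 1L,
       splits = lapply(t$splits, function(s) match(s$left, universe) - 1L))
}

from_cpp_tree <- function(ct, universe) {
  taxa <- universe[ct$taxa + 1L]
  splits <- lapply(ct$splits, function(ix)
    new_split(sort(universe[ix + 1L]), sort(setdiff(taxa, universe[ix + 1L]))))
  mr_tree(taxa, splits, validate = FALSE)
}

validate_inputs <- function(inputs, method) {
  if (length(inputs) == 0L) stop("no input trees")
  for (t in inputs) {
    if (!inherits(t, "mr_tree")) stop("inputs must be mr_tree objects")
    if (method != "minus" && !is_bifurcating(t))
      stop("MR(+) and MR(+)g require bifurcating input trees")
  }
  invisible(inputs)
}

#' Search configuration
#'
#' @param method see [mr_method()].
#' @param tdr_fraction fraction of taxa deleted by one TDR move (default
#'   0.25).
#' @param max_iterations exploration-stage cap; default `l^2` where `l` is
#'   the inner-split count of a bifurcating supertree on the taxon union.
#' @param discard_limit consecutive rejected TDR restarts before the
#'   broadening stage starts; default `l`.
#' @param max_trees cap on the number of equal-scoring trees collected.
#' @param max_returned_trees cap on the number of optimal trees
#'   materialized as R objects (the strict consensus and the optimum count
#'   always cover the complete collected set).
#' @param seed optional RNG seed used for the whole search.
#' @param starting_tree optional user-supplied bifurcating starting tree.
#' @param contract apply the majority-contraction step in [mr_supertree()];
#'   turning it off gives the "-version" methods whose supertree is the
#'   plain strict consensus.
#' @return a list of class `mr_search_config`.
#' @export
search_config <- function(method = "minus", tdr_fraction = 0.25,
                          max_iterations = NULL, discard_limit = NULL,
                          max_trees = 1e5, max_returned_trees = 2000,
                          seed = NULL, starting_tree = NULL,
                          contract = TRUE) {
  method <- mr_method(method)
  stopifnot(tdr_fraction > 0, tdr_fraction < 1, max_trees >= 1,
            max_returned_trees >= 1)
  structure(list(method = method, tdr_fraction = tdr_fraction,
                 max_iterations = max_iterations,
                 discard_limit = discard_limit, max_trees = max_trees,
                 max_returned_trees = max_returned_trees,
                 seed = seed, starting_tree = starting_tree,
                 contract = isTRUE(contract)),
            class = "mr_search_config")
}

#' Step-wise addition starting tree
#'
#' Processes a random taxon order: the first four taxa get the quartet
#' topology most frequent among the input trees; every remaining taxon is
#' inserted at the attachment point minimizing the method's criterion over
#' the informative inputs (those containing the taxon and at least three
#' already placed taxa).  Ties are resolved uniformly at random.
#'
#' @param inputs list of `mr_tree`.
#' @param method see [mr_method()].
#' @param seed optional RNG seed.
#' @return a bifurcating `mr_tree` on the taxon union.
#' @export
stepwise_addition_tree <- function(inputs, method = "minus", seed = NULL) {
  method <- mr_method(method)
  validate_inputs(inputs, method)
  if (!is.null(seed)) set.seed(seed)
  universe <- taxon_union(inputs)
  if (length(universe) < 4L) stop("need at least 4 taxa in the union")
  ct <- cpp_stepwise(as_cpp_inputs(inputs, universe),
                     seq_along(universe) - 1L, method_code(method))
  from_cpp_tree(ct, universe)
}

#' The two NNI alternatives of an inner split
#'
#' @param t a bifurcating `mr_tree`.
#' @param s an inner split of `t`.
#' @return list of the two trees obtained by replacing `s` with each
#'   alternative split across that edge; both differ from `t` by exactly
#'   that split (RF distance 2).
#' @export
nni_variants <- function(t, s) {
  if (!is_bifurcating(t)) stop("NNI requires a bifurcating tree")
  keys <- tree_split_keys(t)
  i <- match(split_key(s), keys)
  if (is.na(i)) stop("split is not an inner split of the tree")
  A <- s$left; B <- s$right
  max_sub <- function(side) {
    best <- NULL
    for (j in seq_along(t$splits)) {
      if (j == i) next
      for (d in list(t$splits[[j]]$left, t$splits[[j]]$right)) {
        if (length(d) < length(side) && all(d %in% side) &&
            (is.null(best) || length(d) > length(best))) best <- d
      }
    }
    if (is.null(best)) best <- side[1L]
    best
  }
  A1 <- max_sub(A); B1 <- max_sub(B)
  A2 <- setdiff(A, A1); B2 <- setdiff(B, B1)
  mk <- function(side) {
    newsp <- t$splits
    newsp[[i]] <- new_split(sort(side), sort(setdiff(t$taxa, side)))
    mr_tree(t$taxa, newsp, validate = FALSE)
  }
  list(mk(c(A1, B1)), mk(c(A1, B2)))
}

#' NNI hill-climb to a local optimum
#'
#' Repeatedly replaces inner splits whose NNI alternative strictly lowers
#' the total score until no improving move exists; equal-scoring
#' alternatives of the final tree are also returned.  All returned trees
#' share one score.
#'
#' @param t bifurcating starting tree spanning the input-taxon union.
#' @param inputs list of `mr_tree`.
#' @param method see [mr_method()].
#' @param seed optional RNG seed (sweep order is randomized).
#' @return list with `trees` (all at the final score), `score`, and
#'   `replacements`.
#' @export
nni_sweep <- function(t, inputs, method = "minus", seed = NULL) {
  method <- mr_method(method)
  validate_inputs(inputs, method)
  if (!is.null(seed)) set.seed(seed)
  universe <- taxon_union(inputs)
  stopifnot(identical(t$taxa, universe), is_bifurcating(t))
  res <- cpp_nni_sweep(as_cpp_tree(t, universe),
                       as_cpp_inputs(inputs, universe), method_code(method))
  list(trees = lapply(res$trees, from_cpp_tree, universe = universe),
       score = res$score, replacements = res$replacements)
}

#' One taxa-deletion-reinsertion move
#'
#' Deletes `ceiling(fraction * n)` random taxa (never going below 4
#' remaining) and reinserts them in random order by step-wise addition.
#'
#' @param t bifurcating tree on the full taxon union.
#' @param inputs list of `mr_tree`.
#' @param method see [mr_method()].
#' @param fraction fraction of taxa to delete.
#' @param seed optional RNG seed.
#' @return a bifurcating `mr_tree` on the same taxa.
#' @export
tdr_step <- function(t, inputs, method = "minus", fraction = 0.25,
                     seed = NULL) {
  method <- mr_method(method)
  validate_inputs(inputs, method)
  if (!is.null(seed)) set.seed(seed)
  universe <- taxon_union(inputs)
  stopifnot(identical(t$taxa, universe), is_bifurcating(t))
  ct <- cpp_tdr(as_cpp_tree(t, universe), as_cpp_inputs(inputs, universe),
                method_code(method), fraction)
  from_cpp_tree(ct, universe)
}

#' Heuristic search for all best-scoring bifurcating supertrees
#'
#' Two stages.  Exploration: the starting tree is NNI-optimized, then the
#' space is explored by repeated TDR restarts, each followed by an NNI
#' hill-climb; a TDR product already seen, or yielding nothing new, counts
#' as a discard.  After `discard_limit` consecutive discards or `l^2`
#' iterations (an iteration is one NNI replacement or one TDR move), the
#' broadening stage NNI-explores every recorded best-scoring tree so the
#' whole optimal neighbourhood is found.
#'
#' @param inputs list of `mr_tree`.
#' @param config an [search_config()] object (or arguments to build one).
#' @return a list of class `mr_search_result`: `best_score`,
#'   `optimal_trees`, `iterations_used`, `stage_log`.
#' @export
run_search <- function(inputs, config = search_config()) {
  if (!inherits(config, "mr_search_config")) config <- do.call(search_config, config)
  validate_inputs(inputs, config$method)
  if (!is.null(config$seed)) set.seed(config$seed)
  universe <- taxon_union(inputs)
  if (length(universe) < 4L) stop("need at least 4 taxa in the union")
  start <- NULL
  if (!is.null(config$starting_tree)) {
    st <- config$starting_tree
    stopifnot(identical(st$taxa, universe), is_bifurcating(st))
    start <- as_cpp_tree(st, universe)
  }
  res <- cpp_run_search(as_cpp_inputs(inputs, universe),
                        seq_along(universe) - 1L,
                        method_code(config$method), config$tdr_fraction,
                        as.integer(config$max_iterations %||% 0L),
                        as.integer(config$discard_limit %||% 0L),
                        as.integer(config$max_trees),
                        as.integer(config$max_returned_trees), start)
  if (isTRUE(res$truncated))
    warning("equal-scoring tree collection hit max_trees; ",
            "the optimal set may be incomplete")
  if (res$n_optimal > length(res$trees))
    warning(res$n_optimal, " optimal trees found; only ",
            length(res$trees), " materialized (max_returned_trees); ",
            "strict_consensus and n_optimal cover the full set")
  trees <- lapply(res$trees, from_cpp_tree, universe = universe)
  ## re-verify the result contract: full span, bifurcating, score agreement
  cin <- as_cpp_inputs(inputs, universe)
  for (tr in trees) {
    stopifnot(identical(tr$taxa, universe), is_bifurcating(tr))
    sc <- cpp_score(as_cpp_tree(tr, universe), cin, method_code(config$method))
    if (sc != res$best_score)
      stop("internal: returned tree does not re-score to best_score")
  }
  cons <- mr_tree(universe, lapply(res$consensus, function(ix)
    new_split(sort(universe[ix + 1L]),
              sort(setdiff(universe, universe[ix + 1L])))),
    validate = FALSE)
  ## (the MR(-) scorer is prune-and-RF, so the constant multifurcation
  ## term of the inputs is already part of best_score)
  structure(list(best_score = res$best_score,
                 optimal_trees = trees,
                 n_optimal = res$n_optimal,
                 strict_consensus = cons,
                 iterations_used = res$iterations,
                 stage_log = list(n_tdr = res$n_tdr,
                                  discards = res$discards,
                                  truncated = isTRUE(res$truncated))),
            class = "mr_search_result")
}

#' @export
print.mr_search_result <- function(x, ...) {
  cat(sprintf("mr_search_result: best score %d, %d optimal tree(s), %d iterations\n",
              x$best_score, x$n_optimal %||% length(x$optimal_trees),
              x$iterations_used))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
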