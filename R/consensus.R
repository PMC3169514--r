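## Post-processing of the optimal tree set: strict consensus, deletion of
## majority-contradicted splits, and x/y support labels.

#' Strict consensus of a set of trees
#'
#' The tree containing exactly the splits present in every input tree.
#'
#' @param trees non-empty list of `mr_tree` on one taxon set.
#' @return an `mr_tree` (possibly multifurcating).
#' @export
strict_consensus <- function(trees) {
  if (length(trees) == 0L) stop("empty tree list")
  taxa <- trees[[1L]]$taxa
  for (t in trees) if (!identical(t$taxa, taxa))
    stop("strict consensus requires identical taxon sets")
  keep <- trees[[1L]]$splits
  keys <- tree_split_keys(trees[[1L]])
  for (t in trees[-1L]) {
    ink <- keys %in% tree_split_keys(t)
    keep <- keep[ink]
    keys <- keys[ink]
    if (length(keep) == 0L) break
  }
  mr_tree(taxa, keep, validate = FALSE)
}

#' Number of input trees contradicting a split
#'
#' An input tree contradicts a split iff it contains at least one split
#' incompatible with it (compatibility is tested after restriction to the
#' shared taxa, so trees sharing fewer than 3 taxa never contradict).
#'
#' @param s an `mr_split`.
#' @param inputs list of `mr_tree`.
#' @return integer count.
#' @export
contradiction_count <- function(s, inputs) {
  sum(vapply(inputs, function(G)
    any(vapply(G$splits, function(g) !are_compatible(g, s), logical(1))),
    logical(1)))
}

#' Delete splits contradicted by at least half of the input trees
#'
#' The contraction step restoring the majority-rule property: every inner
#' split whose contradiction fraction is `>= 0.5` (denominator = total
#' number of input trees) is removed.
#'
#' @param t an `mr_tree`.
#' @param inputs list of `mr_tree`.
#' @return an `mr_tree` (possibly multifurcating).
#' @export
contract_majority_violations <- function(t, inputs) {
  k <- length(inputs)
  if (k == 0L) return(t)
  keep <- Filter(function(s) contradiction_count(s, inputs) / k < 0.5,
                 t$splits)
  mr_tree(t$taxa, keep, validate = FALSE)
}

#' x/y support labels
#'
#' Each split is labeled `x/y` where `x` is the number of input trees not
#' contradicting it and `y` the number of input trees containing a
#' nontrivial split supporting it (a subsplit); `x - y` counts the trees
#' irrelevant for the split.
#'
#' @param t an `mr_tree` (typically the final supertree).
#' @param inputs list of `mr_tree`.
#' @return a list keyed by internal split key; each element has fields
#'   `split`, `x`, `y`, `label`.  Pass directly to [write_newick()] via
#'   [format_support_labels()].
#' @export
support_labels <- function(t, inputs) {
  k <- length(inputs)
  out <- list()
  for (s in t$splits) {
    x <- k - contradiction_count(s, inputs)
    y <- sum(vapply(inputs, function(G)
      any(vapply(G$splits, function(g) is_subsplit(g, s), logical(1))),
      logical(1)))
    out[[split_key(s)]] <- list(split = s, x = x, y = y,
                                label = paste0(x, "/", y))
  }
  out
}

#' Collapse support labels to the named character vector used by
#' [write_newick()]
#' @param labels result of [support_labels()].
#' @export
format_support_labels <- function(labels) {
  vapply(labels, function(l) l$label, character(1))
}

#' Compute a majority-rule supertree
#'
#' The full pipeline: starting tree, heuristic search for all best-scoring
#' bifurcating supertrees, strict consensus, and (unless
#' `config$contract` is off, which yields the "-version" methods)
#' contraction of majority-contradicted splits.  The final tree is labeled
#' with x/y support values.
#'
#' @param inputs list of `mr_tree`.
#' @param config an [search_config()].
#' @param exhaustive replace the heuristic by exhaustive enumeration
#'   (taxon union of at most 8; used for certification).
#' @return list of class `mr_supertree_result`: `supertree` (the final,
#'   possibly multifurcating `mr_tree`), `labels`, `search` (the
#'   [run_search()] result), `newick`.
#' @export
mr_supertree <- function(inputs, config = search_config(),
                         exhaustive = FALSE) {
  if (!inherits(config, "mr_search_config")) config <- do.call(search_config, config)
  if (exhaustive) {
    if (!is.null(config$seed)) set.seed(config$seed)
    ex <- exhaustive_supertree(inputs, config$method)
    search <- structure(list(best_score = ex$best_score,
                             optimal_trees = ex$optimal_trees,
                             n_optimal = length(ex$optimal_trees),
                             strict_consensus =
                               strict_consensus(ex$optimal_trees),
                             iterations_used = NA_integer_,
                             stage_log = list(exhaustive = TRUE)),
                        class = "mr_search_result")
  } else {
    search <- run_search(inputs, config)
  }
  ## the search result's consensus covers the complete optimum set even
  ## when only a sample of trees was materialized
  cons <- search$strict_consensus
  final <- if (config$contract)
    contract_majority_violations(cons, inputs) else cons
  labels <- support_labels(final, inputs)
  structure(list(supertree = final, labels = labels, search = search,
                 newick = write_newick(final, format_support_labels(labels))),
            class = "mr_supertree_result")
}

#' @export
print.mr_supertree_result <- function(x, ...) {
  cat(sprintf("MR supertree: score %d, %d optimal tree(s), %d inner split(s)\n",
              x$search$best_score, x$search$n_optimal,
              length(x$supertree$splits)))
  cat(x$newick, "\n")
  invisible(x)
}
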