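#' Parse a Newick string into a tree
#'
#' Branch lengths and internal-node labels are read and discarded: the
#' methods in this package are purely topological.  Degree-2 nodes are
#' suppressed, so rooted inputs are silently unrooted; to preserve the
#' position of the root, set `treat_root_as_taxon` and an artificial taxon
#' is attached at the root before unrooting.
#'
#' @param text a single Newick statement (terminated by `;`).
#' @param treat_root_as_taxon attach an artificial taxon at the root.
#' @param root_label label used for the artificial root taxon.
#' @return an `mr_tree`.
#' @export
parse_newick <- function(text, treat_root_as_taxon = FALSE,
                         root_label = "ROOT") {
  text <- trimws(text)
  if (treat_root_as_taxon) {
    body <- sub(";\\s*$", "", text)
    text <- paste0("(", body, ",", root_label, ");")
  }
  ph <- ape::read.tree(text = text)
  if (is.null(ph)) stop("invalid Newick string")
  phylo_to_tree(ph)
}

## convert an ape "phylo" object to an mr_tree
phylo_to_tree <- function(ph) {
  ph <- ape::collapse.singles(ph)
  labs <- ph$tip.label
  if (anyDuplicated(labs)) stop("duplicate taxon labels in Newick input")
  n <- length(labs)
  if (n < 3L) stop("fewer than 3 taxa after normalization")
  nnode <- ph$Nnode
  ## accumulate the tip set below every node (postorder)
  ph <- stats::reorder(ph, "postorder")
  below <- vector("list", n + nnode)
  for (i in seq_len(n)) below[[i]] <- labs[i]
  for (k in seq_len(nrow(ph$edge))) {
    p <- ph$edge[k, 1L]; ch <- ph$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  splits <- list()
  seen <- character(0)
  for (k in seq_len(nrow(ph$edge))) {
    ch <- ph$edge[k, 2L]
    if (ch <= n) next                       # terminal edge
    side <- below[[ch]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    s <- new_split(sort(side), sort(setdiff(labs, side)))
    k2 <- split_key(s)
    if (k2 %in% seen) next
    seen <- c(seen, k2)
    splits[[length(splits) + 1L]] <- s
  }
  mr_tree(labs, splits, validate = FALSE)
}

#' Read a multi-tree Newick file
#'
#' One tree per semicolon-terminated statement; blank lines are ignored.
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick text (possibly several statements).
#' @param treat_root_as_taxon,root_label see [parse_newick()].
#' @param drop_uninformative drop trees with zero inner splits, with a
#'   warning (such trees carry no split information).
#' @return list of `mr_tree`.
#' @export
read_newick <- function(file = NULL, text = NULL,
                        treat_root_as_taxon = FALSE, root_label = "ROOT",
                        drop_uninformative = FALSE) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "\n")
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("no trees in input")
  trees <- lapply(parts, function(p)
    parse_newick(paste0(p, ";"), treat_root_as_taxon, root_label))
  if (drop_uninformative) {
    keep <- vapply(trees, function(t) length(t$splits) > 0L, logical(1))
    if (any(!keep))
      warning(sum(!keep), " tree(s) with no inner splits dropped")
    trees <- trees[keep]
    if (length(trees) == 0L) stop("no informative trees left")
  }
  trees
}

#' Write a tree as a Newick string
#'
#' Optionally annotates internal nodes with per-split labels (e.g. the
#' `x/y` support labels of [support_labels()]).  The output re-parses to
#' the identical canonical split set.
#'
#' @param tree an `mr_tree`.
#' @param labels optional named character vector mapping split keys (as
#'   produced internally) to label strings, or the result of
#'   [support_labels()].
#' @param file optional path; when given the string is written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, labels = NULL, file = NULL) {
  lab_for <- function(cluster) {
    if (is.null(labels)) return("")
    s <- new_split(sort(cluster), sort(setdiff(tree$taxa, cluster)))
    v <- unname(labels[split_key(s)])
    if (length(v) == 0L || is.na(v)) "" else as.character(v)
  }
  st <- tree_nesting(tree)
  render <- function(i) {
    kids <- vapply(st$nodes[[i]]$children, function(j) render(j), character(1))
    leaves <- names(st$leaf_parent)[st$leaf_parent == i]
    inner <- paste(c(kids, leaves), collapse = ",")
    paste0("(", inner, ")", lab_for(st$nodes[[i]]$taxa))
  }
  top <- vapply(st$roots, function(j) render(j), character(1))
  top_leaves <- names(st$leaf_parent)[st$leaf_parent == 0L]
  out <- paste0("(", paste(c(top, top_leaves, st$ref), collapse = ","), ");")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
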