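#' Construct an unrooted phylogenetic tree from its split set
#'
#' A tree is identified by its taxon set together with its set of
#' non-trivial (inner) splits; terminal splits are implied by the taxa.
#' A tree on `n` taxa has at most `n - 3` inner splits and is
#' \emph{bifurcating} iff it has exactly `n - 3`.
#'
#' @param taxa character vector of unique taxon labels (at least 3).
#' @param splits list of `mr_split` objects, each partitioning exactly
#'   `taxa`, pairwise compatible and non-trivial.  The given order is kept.
#' @param validate check invariants (disable for trusted internal calls).
#' @return an object of class `mr_tree` with elements `taxa` (sorted) and
#'   `splits`.
#' @examples
#' t <- mr_tree(c("C", "D", "F", "G", "H"),
#'              list(mr_split(c("D", "F"), c("C", "G", "H")),
#'                   mr_split(c("G", "H"), c("C", "D", "F"))))
#' is_bifurcating(t)
#' @export
mr_tree <- function(taxa, splits = list(), validate = TRUE) {
  taxa <- sort(as.character(taxa))
  if (validate) {
    if (length(taxa) < 3L) stop("a tree needs at least 3 taxa")
    if (anyDuplicated(taxa)) stop("duplicate taxon labels")
    if (any(!nzchar(taxa))) stop("empty taxon labels")
    for (s in splits) {
      if (!inherits(s, "mr_split")) stop("splits must be mr_split objects")
      if (!identical(split_universe(s), taxa))
        stop("split universe does not match the tree's taxa: ", format(s))
      if (is_trivial_split(s))
        stop("inner splits must be non-trivial: ", format(s))
    }
    keys <- vapply(splits, split_key, character(1))
    if (anyDuplicated(keys)) stop("duplicate splits")
    if (length(splits) > length(taxa) - 3L)
      stop("more than n - 3 inner splits")
    if (length(splits) > 1L) {
      for (i in seq_len(length(splits) - 1L))
        for (j in (i + 1L):length(splits))
          if (!are_compatible(splits[[i]], splits[[j]]))
            stop("incompatible splits: ", format(splits[[i]]), " vs ",
                 format(splits[[j]]))
    }
  }
  structure(list(taxa = taxa, splits = splits), class = "mr_tree")
}

#' @export
print.mr_tree <- function(x, ...) {
  cat(sprintf("mr_tree: %d taxa, %d inner splits (%s)\n",
              length(x$taxa), length(x$splits),
              if (is_bifurcating(x)) "bifurcating" else "multifurcating"))
  for (s in x$splits) cat("  ", format(s), "\n", sep = "")
  invisible(x)
}

#' Number of taxa of a tree
#' @param t an `mr_tree`.
#' @export
n_taxa <- function(t) length(t$taxa)

#' Is the tree fully resolved?
#' @param t an `mr_tree`.
#' @return `TRUE` iff the tree has exactly `n - 3` inner splits.
#' @export
is_bifurcating <- function(t) length(t$splits) == length(t$taxa) - 3L

#' Multifurcation count
#'
#' The number of missing inner edges, `m = (n - 3) - |inner splits|`;
#' 0 for a bifurcating tree.
#'
#' @param t an `mr_tree`.
#' @export
multifurcations <- function(t) length(t$taxa) - 3L - length(t$splits)

#' Splits of a tree
#' @param t an `mr_tree`.
#' @param trivial also include the terminal splits (one per taxon).
#' @return list of `mr_split`.
#' @export
tree_splits <- function(t, trivial = FALSE) {
  if (!trivial) return(t$splits)
  c(t$splits, lapply(t$taxa, function(x)
    new_split(x, setdiff(t$taxa, x))))
}

tree_split_keys <- function(t) vapply(t$splits, split_key, character(1))

## canonical identity key of a tree (taxa + sorted split keys)
tree_key <- function(t) {
  paste(c(paste(t$taxa, collapse = "\x1f"), sort(tree_split_keys(t))),
        collapse = "\x1d")
}

#' Test two trees for topological identity
#' @param t1,t2 `mr_tree` objects.
#' @return `TRUE` iff both trees have the same taxa and the same split set.
#' @export
same_tree <- function(t1, t2) identical(tree_key(t1), tree_key(t2))

#' Restrict a tree to a taxon subset
#'
#' Every split is restricted to `taxa`; vanished and now-trivial splits
#' are dropped and duplicates removed.
#'
#' @param t an `mr_tree`.
#' @param taxa character vector; at least 3 of them must occur in `t`.
#' @return an `mr_tree` on the intersection.
#' @export
restrict_tree <- function(t, taxa) {
  keep <- t$taxa[t$taxa %in% taxa]
  if (length(keep) < 3L)
    stop("fewer than 3 shared taxa after restriction")
  out <- list()
  seen <- character(0)
  for (s in t$splits) {
    r <- restrict_split(s, keep)
    if (is.null(r) || is_trivial_split(r)) next
    k <- split_key(r)
    if (k %in% seen) next
    seen <- c(seen, k)
    out[[length(out) + 1L]] <- r
  }
  mr_tree(keep, out, validate = FALSE)
}

#' Robinson-Foulds distance
#'
#' The size of the symmetric difference of the two inner split sets.
#' Defined only for trees on identical taxon sets; an even number when
#' both trees are bifurcating.
#'
#' @param t1,t2 `mr_tree` objects on the same taxa.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!identical(t1$taxa, t2$taxa))
    stop("RF distance requires identical taxon sets")
  k1 <- tree_split_keys(t1)
  k2 <- tree_split_keys(t2)
  sum(!(k1 %in% k2)) + sum(!(k2 %in% k1))
}

## ---- rooted-at-a-leaf structure ------------------------------------------
##
## Orienting every split side away from a reference leaf gives a laminar
## family of clusters; nesting them yields the tree structure used for
## Newick output, node enumeration and leaf attachment.

## clusters: list of sorted character vectors (sides not containing ref),
## ordered so that children come before parents (by size).
tree_clusters <- function(t, ref = t$taxa[1L]) {
  cl <- lapply(t$splits, function(s) if (ref %in% s$left) s$right else s$left)
  cl[order(vapply(cl, length, integer(1)))]
}

## Nested list structure rooted next to `ref`: each node is either a taxon
## label (leaf) or a list of child nodes.  The root children are the
## maximal clusters/leaves plus `ref` itself.
tree_nesting <- function(t, ref = t$taxa[1L]) {
  cl <- tree_clusters(t, ref)
  nodes <- lapply(cl, function(x) list(taxa = x, children = list()))
  free <- setdiff(t$taxa, ref)          # leaves not yet assigned
  roots <- list()
  assigned_leaf <- character(0)
  ## attach each cluster to the smallest strictly containing cluster
  for (i in seq_along(nodes)) {
    ci <- nodes[[i]]$taxa
    parent <- 0L
    if (i < length(nodes)) for (j in (i + 1L):length(nodes)) {
      if (all(ci %in% nodes[[j]]$taxa)) { parent <- j; break }
    }
    if (parent > 0L)
      nodes[[parent]]$children <- c(nodes[[parent]]$children, list(i))
    else
      roots <- c(roots, list(i))
  }
  ## attach leaves to smallest containing cluster
  leaf_parent <- integer(0)
  for (x in free) {
    parent <- 0L
    for (j in seq_along(nodes)) {
      if (x %in% nodes[[j]]$taxa) { parent <- j; break }
    }
    leaf_parent[x] <- parent
  }
  list(nodes = nodes, roots = roots, leaf_parent = leaf_parent, ref = ref)
}

## Inner nodes of the unrooted tree as taxon multipartitions.
## Returns a list; each element is a list of character vectors (the "away"
## sides of the edges meeting at that node) partitioning the taxa.
tree_nodes <- function(t) {
  ref <- t$taxa[1L]
  st <- tree_nesting(t, ref)
  nodes <- st$nodes
  out <- list()
  part_of <- function(i) {                 # direct child parts of cluster i
    kids <- lapply(st$nodes[[i]]$children, function(j) st$nodes[[j]]$taxa)
    leaves <- names(st$leaf_parent)[st$leaf_parent == i]
    c(kids, as.list(leaves))
  }
  for (i in seq_along(nodes)) {
    parts <- part_of(i)
    parts <- c(parts, list(setdiff(t$taxa, nodes[[i]]$taxa)))
    out[[length(out) + 1L]] <- parts
  }
  ## the node adjacent to ref (root of the nesting)
  top <- lapply(st$roots, function(j) st$nodes[[j]]$taxa)
  top_leaves <- names(st$leaf_parent)[st$leaf_parent == 0L]
  out[[length(out) + 1L]] <- c(top, as.list(top_leaves), list(ref))
  out
}

## ---- leaf attachment by split algebra ------------------------------------

## Attach taxon x on the edge given by sides (A, B) of tree t (A|B must be a
## split of t, terminal splits allowed).  Returns a new mr_tree.
attach_leaf_edge <- function(t, x, sideA, sideB) {
  newsp <- lapply(t$splits, function(s) {
    if (all(s$left %in% sideA) || all(s$left %in% sideB))
      new_split(s$left, sort(c(s$right, x)))
    else
      new_split(sort(c(s$left, x)), s$right)
  })
  ## subdividing edge A|B yields the split pair A|B+x and A+x|B; if A|B was
  ## an inner split it transformed into A|B+x above, so add the other; if it
  ## was terminal, add whichever of the pair is non-trivial
  if (length(sideB) > 1L)
    newsp <- c(newsp, list(new_split(sort(c(sideA, x)), sideB)))
  else if (length(sideA) > 1L)
    newsp <- c(newsp, list(new_split(sideA, sort(c(sideB, x)))))
  mr_tree(c(t$taxa, x), newsp, validate = FALSE)
}

## Attach taxon x at an inner node given as a list of "away" sides
## (a partition of t's taxa); creates/grows a multifurcation.
attach_leaf_node <- function(t, x, parts) {
  newsp <- lapply(t$splits, function(s) {
    lin <- vapply(parts, function(p) all(s$left %in% p), logical(1))
    if (any(lin))                        # left side away from the node
      new_split(s$left, sort(c(s$right, x)))
    else
      new_split(sort(c(s$left, x)), s$right)
  })
  mr_tree(c(t$taxa, x), newsp, validate = FALSE)
}

## Remove a taxon from a tree (drop vanished/trivial, dedup).
remove_leaf <- function(t, x) {
  keep <- setdiff(t$taxa, x)
  restrict_tree(t, keep)
}
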