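## Independent brute-force references used to certify the closed-form
## distances and the heuristic search on small instances.

#' Prune-and-RF reference for the MR(-) distance
#'
#' @param S,G `mr_tree` objects with at least 3 shared taxa.
#' @return `RF(S|shared, G|shared)`.
#' @export
d_minus_oracle <- function(S, G) {
  shared <- S$taxa[S$taxa %in% G$taxa]
  rf_distance(restrict_tree(S, shared), restrict_tree(G, shared))
}

## edge list of a tree as list of list(A=, B=) sides (inner + terminal)
tree_edges <- function(t) {
  edges <- lapply(t$splits, function(s) list(A = s$left, B = s$right))
  c(edges, lapply(t$taxa, function(x)
    list(A = x, B = setdiff(t$taxa, x))))
}

#' Enumerate all bifurcating edge-only extensions of a tree
#'
#' Yields every bifurcating tree obtainable by inserting the missing taxa,
#' one at a time, onto any edge (deduplicated by canonical split set).
#' With `k = 1` missing taxon the count equals the number of edges,
#' `2n - 3`.
#'
#' @param G a bifurcating `mr_tree`.
#' @param missing character vector of taxa to add (guard: at most 6).
#' @return list of `mr_tree`.
#' @export
enumerate_edge_extensions <- function(G, missing) {
  if (length(missing) > 6L) stop("more than 6 missing taxa (guard)")
  if (!is_bifurcating(G)) stop("G must be bifurcating")
  current <- list(G)
  for (x in missing) {
    nxt <- list(); seen <- character(0)
    for (t in current) {
      for (e in tree_edges(t)) {
        t2 <- attach_leaf_edge(t, x, e$A, e$B)
        k <- tree_key(t2)
        if (k %in% seen) next
        seen <- c(seen, k)
        nxt[[length(nxt) + 1L]] <- t2
      }
    }
    current <- nxt
  }
  current
}

#' Enumerate all edge-or-node extensions of a tree
#'
#' Additionally allows attaching a missing taxon to an inner node, which
#' creates or grows a multifurcation; multifurcations already present in
#' `G` are never refined.
#'
#' @inheritParams enumerate_edge_extensions
#' @return list of `mr_tree` (possibly multifurcating).
#' @export
enumerate_node_or_edge_extensions <- function(G, missing) {
  if (length(missing) > 6L) stop("more than 6 missing taxa (guard)")
  current <- list(G)
  for (x in missing) {
    nxt <- list(); seen <- character(0)
    add <- function(t2) {
      k <- tree_key(t2)
      if (!(k %in% seen)) {
        seen <<- c(seen, k)
        nxt[[length(nxt) + 1L]] <<- t2
      }
    }
    for (t in current) {
      for (e in tree_edges(t)) add(attach_leaf_edge(t, x, e$A, e$B))
      for (nd in tree_nodes(t)) add(attach_leaf_node(t, x, nd))
    }
    current <- nxt
  }
  current
}

#' Exhaustive MR(+) distance
#'
#' Minimum RF over all bifurcating edge-only extensions of `G` onto the
#' taxa of the dummy-modified supertree.
#'
#' @param S,G bifurcating `mr_tree` objects.
#' @return non-negative integer.
#' @export
d_plus_oracle <- function(S, G) {
  if (!all(G$taxa %in% S$taxa)) G <- restrict_tree(G, S$taxa)
  Sm <- modify_supertree(S, G$taxa)
  missing <- setdiff(Sm$taxa, G$taxa)
  min(vapply(enumerate_edge_extensions(G, missing),
             function(e) rf_distance(e, Sm), integer(1)))
}

#' Exhaustive MR(+)g distance
#'
#' Minimum RF over all edge-or-node extensions of `G` onto the taxa of the
#' dummy-modified supertree.
#'
#' @param S,G bifurcating `mr_tree` objects.
#' @return non-negative integer.
#' @export
d_plus_g_oracle <- function(S, G) {
  if (!all(G$taxa %in% S$taxa)) G <- restrict_tree(G, S$taxa)
  Sm <- modify_supertree(S, G$taxa)
  missing <- setdiff(Sm$taxa, G$taxa)
  min(vapply(enumerate_node_or_edge_extensions(G, missing),
             function(e) rf_distance(e, Sm), integer(1)))
}

#' Constructive optimal edge-or-node extension (good/bad taxa)
#'
#' Builds the witness extension used in the constructive proof of the
#' `B + C` formula: "good" missing taxa hang between supertree edges that
#' restrict to one and the same input-tree split and are placed onto that
#' edge at no cost; the remaining "bad" taxa (`B - C` of them for a
#' bifurcating pair) are placed onto a node adjacent to a conflicting
#' input split, each costing one split.
#'
#' @param S_mod a dummy-modified bifurcating supertree (see
#'   [modify_supertree()]).
#' @param G a bifurcating input tree whose taxa are contained in `S_mod`'s.
#' @return list with `extended_tree` (an `mr_tree` on `S_mod`'s taxa),
#'   `n_good`, `n_bad`, and `achieved_rf`.
#' @export
construct_witness <- function(S_mod, G) {
  T0 <- G$taxa
  stopifnot(all(T0 %in% S_mod$taxa))
  missing <- setdiff(S_mod$taxa, T0)
  ## group supertree splits (inner + terminal) by their restriction to T0
  ssp <- tree_splits(S_mod, trivial = TRUE)
  groups <- list()
  for (s in ssp) {
    r <- restrict_split(s, T0)
    if (is.null(r)) next
    k <- split_key(r)
    groups[[k]] <- c(groups[[k]], list(s))
  }
  gkeys <- vapply(tree_splits(G, trivial = TRUE), split_key, character(1))
  E <- G
  placed <- character(0)
  for (k in names(groups)) {
    grp <- groups[[k]]
    if (length(grp) < 2L || !(k %in% gkeys)) next
    ## orient all group members with the side containing the restriction's
    ## left part first, then sort by that side's size: a path in S_mod
    r <- restrict_split(grp[[1L]], T0)
    sideL <- lapply(grp, function(s)
      if (all(r$left %in% s$left)) s$left else s$right)
    ord <- order(vapply(sideL, length, integer(1)))
    sideL <- sideL[ord]
    ## consecutive differences are single hanging taxa ("good" taxa),
    ## attached along the growing chain mirroring the supertree path
    anchor <- r$left
    for (q in seq_len(length(sideL) - 1L)) {
      diffs <- setdiff(sideL[[q + 1L]], sideL[[q]])
      diffs <- diffs[diffs %in% missing & !(diffs %in% placed)]
      for (x in diffs) {
        A <- find_edge_side(E, anchor, r$left, T0)
        E <- attach_leaf_edge(E, x, A, sort(setdiff(E$taxa, A)))
        anchor <- c(anchor, x)
        placed <- c(placed, x)
      }
    }
  }
  n_good <- length(placed)
  ## remaining taxa are "bad": place each on a node adjacent to an edge of
  ## a conflicting input split
  bad <- setdiff(missing, placed)
  n_bad <- length(bad)
  if (n_bad > 0L) {
    conflicted <- Filter(function(g)
      any(vapply(S_mod$splits, function(s) !are_compatible(g, s), logical(1))),
      G$splits)
    if (length(conflicted) == 0L)
      stop("bad taxa present but no conflicting input split")
    for (x in bad) {
      ## candidate nodes: those adjacent to the edge of a conflicting
      ## split; the admissible one keeps the subsplit matches intact, so
      ## pick the candidate minimizing the partial RF to the supertree
      best <- NULL; bestrf <- Inf
      for (g0 in conflicted) {
        for (nd in find_nodes_adjacent(E, g0)) {
          E2 <- attach_leaf_node(E, x, nd)
          r <- rf_distance(restrict_tree(S_mod, E2$taxa), E2)
          if (r < bestrf) { bestrf <- r; best <- E2 }
        }
      }
      E <- best
    }
  }
  list(extended_tree = E, n_good = n_good, n_bad = n_bad,
       achieved_rf = rf_distance(E, S_mod))
}

## helper: the minimal edge side of E that contains `anchor` and restricts
## to `target_left` on the base taxon set T0
find_edge_side <- function(E, anchor, target_left, T0) {
  best <- NULL
  for (e in tree_edges(E)) {
    for (A in list(e$A, e$B)) {
      if (!all(anchor %in% A)) next
      if (!setequal(A[A %in% T0], target_left)) next
      if (is.null(best) || length(A) < length(best)) best <- A
    }
  }
  if (is.null(best)) stop("internal: path edge not found in witness tree")
  sort(best)
}

## helper: in tree E, the nodes adjacent to the edge whose split restricted
## to g's universe equals g (one per end of the edge)
find_nodes_adjacent <- function(E, g) {
  uni <- split_universe(g)
  out <- list()
  for (nd in tree_nodes(E)) {
    ## a node is adjacent to the edge iff one of its away-parts restricts
    ## to one full side of g (the rest covering the other side)
    for (p in nd) {
      pr <- p[p %in% uni]
      if (length(pr) == 0L) next
      if (setequal(pr, g$left) || setequal(pr, g$right)) {
        rest <- setdiff(unlist(nd), p)
        rr <- rest[rest %in% uni]
        if (setequal(rr, setdiff(uni, pr))) {
          out[[length(out) + 1L]] <- nd
          break
        }
      }
    }
  }
  if (length(out) == 0L) stop("internal: no node adjacent to the edge")
  out
}

#' Enumerate all bifurcating trees on a taxon set
#'
#' There are `(2n - 5)!!` of them (15, 105, 945 for n = 5, 6, 7).
#'
#' @param taxa character vector (3 to 8 taxa).
#' @return list of `mr_tree`.
#' @export
enumerate_bifurcating_trees <- function(taxa) {
  taxa <- sort(as.character(taxa))
  n <- length(taxa)
  if (n < 3L || n > 8L) stop("enumeration supported for 3 to 8 taxa")
  current <- list(mr_tree(taxa[1:3], validate = FALSE))
  for (i in seq_len(n - 3L) + 3L) {
    x <- taxa[i]
    nxt <- list()
    for (t in current)
      for (e in tree_edges(t))
        nxt[[length(nxt) + 1L]] <- attach_leaf_edge(t, x, e$A, e$B)
    current <- nxt
  }
  current
}

#' Exhaustive supertree search
#'
#' Enumerates all bifurcating trees on the union of the input taxa and
#' returns the exact minimum score and every minimizer.
#'
#' @param inputs list of `mr_tree`.
#' @param method see [mr_method()].
#' @return list with `best_score` and `optimal_trees`.
#' @export
exhaustive_supertree <- function(inputs, method = c("minus", "plus", "plusg")) {
  method <- mr_method(method)
  taxa <- sort(unique(unlist(lapply(inputs, function(t) t$taxa))))
  if (length(taxa) > 8L) stop("exhaustive search limited to 8 taxa")
  trees <- enumerate_bifurcating_trees(taxa)
  scores <- vapply(trees, function(s)
    suppressWarnings(total_score(s, inputs, method)), integer(1))
  best <- min(scores)
  list(best_score = best, optimal_trees = trees[scores == best])
}
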