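#' @useDynLib mrsupertree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Create a split (bipartition of a taxon set)
#'
#' A split \eqn{X_1|X_2} is the bipartition of a taxon set induced by
#' removing one edge from an unrooted tree.  Splits are stored in a
#' canonical orientation: the side containing the lexicographically
#' smallest taxon of the split's universe comes first, and both sides are
#' sorted.  A split is \emph{trivial} (terminal) iff one side contains a
#' single taxon.
#'
#' @param side1,side2 character vectors of taxon labels; disjoint, both
#'   non-empty.
#' @return an object of class `mr_split` with elements `left` and `right`.
#' @examples
#' mr_split(c("G", "H"), c("C", "D", "F"))
#' @export
mr_split <- function(side1, side2) {
  side1 <- as.character(side1)
  side2 <- as.character(side2)
  if (length(side1) == 0L || length(side2) == 0L)
    stop("both sides of a split must be non-empty")
  if (anyDuplicated(c(side1, side2)))
    stop("sides of a split must be disjoint sets of unique labels")
  if (any(!nzchar(c(side1, side2))))
    stop("taxon labels must be non-empty strings")
  new_split(sort(side1), sort(side2))
}

## internal constructor: assumes sorted, disjoint, non-empty sides
new_split <- function(side1, side2) {
  if (side1[1L] > side2[1L]) {
    tmp <- side1; side1 <- side2; side2 <- tmp
  }
  structure(list(left = side1, right = side2), class = "mr_split")
}

#' @export
print.mr_split <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.mr_split <- function(x, ...) {
  paste0(paste(x$left, collapse = ","), " | ", paste(x$right, collapse = ","))
}

## canonical hash key of a split (character scalar)
split_key <- function(s) {
  paste(paste(s$left, collapse = "\x1f"), paste(s$right, collapse = "\x1f"),
        sep = "\x1e")
}

#' Taxon universe of a split
#' @param s an `mr_split`.
#' @return sorted character vector of all taxa the split partitions.
#' @export
split_universe <- function(s) sort(c(s$left, s$right))

#' Is a split trivial (terminal)?
#' @param s an `mr_split`.
#' @return `TRUE` iff one side has exactly one taxon.
#' @export
is_trivial_split <- function(s) {
  length(s$left) == 1L || length(s$right) == 1L
}

#' Restrict a split to a taxon subset
#'
#' Both sides are intersected with `taxa`.  If either side becomes empty
#' the split vanishes and `NULL` is returned.
#'
#' @param s an `mr_split`.
#' @param taxa character vector of taxa to keep.
#' @return an `mr_split`, or `NULL` if the split vanishes.
#' @export
restrict_split <- function(s, taxa) {
  l <- s$left[s$left %in% taxa]
  r <- s$right[s$right %in% taxa]
  if (length(l) == 0L || length(r) == 0L) return(NULL)
  new_split(l, r)
}

#' Test compatibility of two splits
#'
#' Two splits are compatible iff they can occur together in one tree, i.e.
#' at least one of the four side intersections is empty.  Splits on
#' different taxon sets are first restricted to the shared taxa; a split
#' that vanishes or becomes trivial under restriction is compatible with
#' anything.
#'
#' @param s1,s2 `mr_split` objects (universes may differ).
#' @return logical.
#' @export
are_compatible <- function(s1, s2) {
  u1 <- c(s1$left, s1$right)
  u2 <- c(s2$left, s2$right)
  shared <- u1[u1 %in% u2]
  a <- restrict_split(s1, shared)
  b <- restrict_split(s2, shared)
  if (is.null(a) || is.null(b)) return(TRUE)
  if (is_trivial_split(a) || is_trivial_split(b)) return(TRUE)
  !(any(a$left %in% b$left) && any(a$left %in% b$right) &&
    any(a$right %in% b$left) && any(a$right %in% b$right))
}

#' Test the subsplit relation
#'
#' A partial split \eqn{Y_1|Y_2} is a subsplit of a plenary split
#' \eqn{Z_1|Z_2} iff \eqn{Y_1 \subseteq Z_1, Y_2 \subseteq Z_2} or
#' \eqn{Y_1 \subseteq Z_2, Y_2 \subseteq Z_1}.
#'
#' @param partial an `mr_split` whose taxa are a subset of `plenary`'s taxa.
#' @param plenary an `mr_split`.
#' @return logical.
#' @export
is_subsplit <- function(partial, plenary) {
  (all(partial$left %in% plenary$left) && all(partial$right %in% plenary$right)) ||
  (all(partial$left %in% plenary$right) && all(partial$right %in% plenary$left))
}
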