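## shared fixtures and generators (all built in code)

## the 8-taxon worked example: supertree and overlapping 5-taxon input tree
example_supertree <- function() {
  mr_tree(LETTERS[1:8], list(
    mr_split(c("A", "B"), LETTERS[3:8]),
    mr_split(c("A", "B", "C"), LETTERS[4:8]),
    mr_split(c("A", "B", "C", "D"), LETTERS[5:8]),
    mr_split(c("F", "G", "H"), LETTERS[1:5]),
    mr_split(c("G", "H"), LETTERS[1:6])))
}

example_input <- function() {
  mr_tree(c("C", "D", "F", "G", "H"), list(
    mr_split(c("D", "F"), c("C", "G", "H")),
    mr_split(c("G", "H"), c("C", "D", "F"))))
}

## random bifurcating tree by sequential random edge insertion
random_bifurcating <- function(taxa) {
  taxa <- sample(taxa)
  t <- mr_tree(taxa[1:3], validate = FALSE)
  for (x in taxa[-(1:3)]) {
    e <- mrsupertree:::tree_edges(t)[[sample.int(2L * n_taxa(t) - 3L, 1L)]]
    t <- mrsupertree:::attach_leaf_edge(t, x, e$A, e$B)
  }
  t
}

## random (supertree, input) pair: S on n taxa, G bifurcating on a random
## subset of size n_g
random_pair <- function(n, n_g) {
  taxa <- paste0("x", seq_len(n))
  S <- random_bifurcating(taxa)
  G <- random_bifurcating(sample(taxa, n_g))
  list(S = S, G = G)
}

expect_same_tree_set <- function(a, b) {
  ka <- sort(vapply(a, mrsupertree:::tree_key, character(1)))
  kb <- sort(vapply(b, mrsupertree:::tree_key, character(1)))
  expect_identical(ka, kb)
}
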