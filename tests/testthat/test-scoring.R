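test_that("modify_supertree collapses exactly the input-free subtrees", {
  S <- example_supertree()
  G <- example_input()
  Sm <- modify_supertree(S, G$taxa)
  ## {A, B} is replaced by one dummy; E stays (terminal, never collapsed)
  dummies <- grep("^__mrst_dummy_", Sm$taxa, value = TRUE)
  expect_length(dummies, 1)
  expect_identical(sort(setdiff(Sm$taxa, dummies)),
                   c("C", "D", "E", "F", "G", "H"))
  expect_true(is_bifurcating(Sm))
  expect_length(Sm$splits, 4)
  ## restriction to the input taxa is unchanged by the modification
  expect_true(same_tree(restrict_tree(Sm, G$taxa), restrict_tree(S, G$taxa)))
  ## nothing to collapse
  expect_true(same_tree(modify_supertree(S, S$taxa), S))
  ## caterpillar: three leading taxa collapse into one dummy
  cat6 <- mr_tree(LETTERS[1:6], list(
    mr_split(c("A", "B"), LETTERS[3:6]),
    mr_split(c("A", "B", "C"), LETTERS[4:6]),
    mr_split(c("A", "B", "C", "D"), LETTERS[5:6])))
  m <- modify_supertree(cat6, c("D", "E", "F"))
  expect_identical(n_taxa(m), 4L)
  expect_true(is_bifurcating(m))
})

test_that("relationship matrix reproduces the printed example", {
  S <- example_supertree()
  G <- example_input()
  ## unmodified pair: row/column order as constructed
  M0 <- build_relationship_matrix(G, S)
  expect_identical(unname(M0["g1", ]), c("c", "c", "i", "i", "c"))
  expect_identical(unname(M0["g2", ]), c("c", "c", "c", "c", "s"))
  expect_identical(attr(M0, "c"), c(1L, 0L))
  expect_identical(attr(M0, "b"), c(0L, 0L, 1L, 1L, 0L))
  ## modified pair: C = 1 (only g1 conflicted), B = 2
  Sm <- modify_supertree(S, G$taxa)
  M1 <- build_relationship_matrix(G, Sm)
  expect_identical(sum(attr(M1, "c")), 1L)
  expect_identical(attr(M1, "c")[1], 1L)
  expect_identical(conflict_counts(M1), c(C = 1L, B = 2L))
  ## a displayed input tree has no conflicts and a subsplit in every row
  Gd <- restrict_tree(S, c("A", "C", "E", "G", "H"))
  M2 <- build_relationship_matrix(Gd, S)
  expect_identical(sum(attr(M2, "c")), 0L)
  expect_identical(sum(attr(M2, "b")), 0L)
  expect_true(all(apply(unclass(M2) == "s", 1, any)))
})

test_that("including trivial splits never changes C or B", {
  set.seed(21)
  S <- example_supertree(); G <- example_input()
  Sm <- modify_supertree(S, G$taxa)
  expect_identical(conflict_counts(build_relationship_matrix(G, Sm)),
                   conflict_counts(build_relationship_matrix(G, Sm,
                                                             include_trivial = TRUE)))
  for (rep in 1:10) {
    p <- random_pair(8, 6)
    Sm <- modify_supertree(p$S, p$G$taxa)
    expect_identical(conflict_counts(build_relationship_matrix(p$G, Sm)),
                     conflict_counts(build_relationship_matrix(p$G, Sm,
                                                               include_trivial = TRUE)))
  }
})

test_that("worked-example distances: d- = 2, d+g = 3, d+ = 4", {
  S <- example_supertree()
  G <- example_input()
  expect_identical(d_minus(S, G), 2L)
  expect_identical(d_plus_g(S, G), 3L)
  expect_identical(d_plus(S, G), 4L)
  ## a displayed subtree scores 0 under all methods
  Gd <- restrict_tree(S, c("B", "C", "D", "F", "H"))
  expect_identical(d_minus(S, Gd), 0L)
  expect_identical(d_plus_g(S, Gd), 0L)
  expect_identical(d_plus(S, Gd), 0L)
})

test_that("d- is modification-neutral and equals prune-and-RF (property)", {
  set.seed(31)
  for (rep in 1:60) {
    p <- random_pair(sample(7:12, 1), sample(4:6, 1))
    expect_identical(d_minus(p$S, p$G), d_minus_oracle(p$S, p$G))
    ## computing C on the modified supertree makes no difference
    Sm <- modify_supertree(p$S, p$G$taxa)
    cc <- conflict_counts(build_relationship_matrix(p$G, Sm))
    expect_identical(d_minus(p$S, p$G), unname(2L * cc["C"]))
  }
})

test_that("ordering d- <= d+g <= d+ and B >= C after modification (property)", {
  set.seed(41)
  for (rep in 1:120) {
    p <- random_pair(sample(6:11, 1), sample(4:6, 1))
    dm <- d_minus(p$S, p$G); dg <- d_plus_g(p$S, p$G); dp <- d_plus(p$S, p$G)
    expect_lte(dm, dg)
    expect_lte(dg, dp)
    cc <- conflict_counts(build_relationship_matrix(
      p$G, modify_supertree(p$S, p$G$taxa)))
    expect_gte(cc[["B"]], cc[["C"]])
  }
})

test_that("consensus setting: all three distances collapse to RF", {
  set.seed(51)
  taxa <- paste0("t", 1:6)
  for (rep in 1:40) {
    S <- random_bifurcating(taxa); G <- random_bifurcating(taxa)
    d <- rf_distance(S, G)
    expect_identical(d_minus(S, G), d)
    expect_identical(d_plus_g(S, G), d)
    expect_identical(d_plus(S, G), d)
    ## C = B = d / 2 in the consensus setting
    cc <- conflict_counts(build_relationship_matrix(G, S))
    expect_identical(unname(cc["C"]), d %/% 2L)
    expect_identical(unname(cc["B"]), d %/% 2L)
  }
})

test_that("MR(-) handles multifurcating input trees (2C + m)", {
  set.seed(61)
  for (rep in 1:20) {
    S <- random_bifurcating(paste0("t", 1:9))
    G0 <- restrict_tree(S, sample(S$taxa, 6))
    drop <- sample.int(length(G0$splits), 1)
    G <- mr_tree(G0$taxa, G0$splits[-drop], validate = FALSE)
    expect_identical(multifurcations(G), 1L)
    expect_identical(d_minus(S, G), d_minus_oracle(S, G))
    expect_identical(d_minus(S, G) %% 2L, 1L)   # 2C + m with m = 1 is odd
  }
})

test_that("total_score sums per-tree distances; degenerate overlaps warn", {
  S <- example_supertree()
  G <- example_input()
  expect_identical(total_score(S, list(G), "minus"), 2L)
  expect_identical(total_score(S, list(G, G), "plus"), 8L)   # additivity
  inputs <- lapply(1:3, function(i) restrict_tree(S, sample(S$taxa, 5)))
  for (m in c("minus", "plus", "plusg"))
    expect_identical(total_score(S, inputs, m), 0L)
  ## missing taxon in the supertree is an error
  expect_error(total_score(restrict_tree(S, LETTERS[1:6]), list(G),
                           "minus"), "missing taxa")
})
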