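test_that("single input tree: stepwise addition and search return it", {
  set.seed(121)
  t <- random_bifurcating(paste0("t", 1:10))
  st <- stepwise_addition_tree(list(t), "minus", seed = 1)
  expect_true(same_tree(st, t))
  for (m in c("minus", "plus", "plusg")) {
    res <- run_search(list(t), search_config(method = m, seed = 2))
    expect_identical(res$best_score, 0L)
    expect_length(res$optimal_trees, 1)
    expect_true(same_tree(res$optimal_trees[[1]], t))
  }
})

test_that("stepwise addition is deterministic under a fixed seed and finds", {
  ## 10 input trees at 25% deletion, the published compatible setting
  set.seed(131)
  model <- random_bifurcating(paste0("t", 1:16))
  inputs <- lapply(1:10, function(i) restrict_tree(model, sample(model$taxa, 12)))
  a <- stepwise_addition_tree(inputs, "minus", seed = 5)
  b <- stepwise_addition_tree(inputs, "minus", seed = 5)
  expect_true(same_tree(a, b))
  ## compatible restrictions: the start tree usually already scores 0
  hits <- 0
  for (s in 1:20) {
    st <- stepwise_addition_tree(inputs, "minus", seed = 100 + s)
    if (total_score(st, inputs, "minus") == 0L) hits <- hits + 1
  }
  expect_gte(hits, 18)   # >= 90% of seeded runs
})

test_that("nni_variants produces the two alternative topologies", {
  q <- mr_tree(c("A", "B", "C", "D"),
               list(mr_split(c("A", "B"), c("C", "D"))))
  v <- nni_variants(q, q$splits[[1]])
  keys <- sort(vapply(v, mrsupertree:::tree_key, character(1)))
  expected <- sort(c(
    mrsupertree:::tree_key(mr_tree(q$taxa, list(mr_split(c("A", "C"), c("B", "D"))))),
    mrsupertree:::tree_key(mr_tree(q$taxa, list(mr_split(c("A", "D"), c("B", "C")))))))
  expect_identical(keys, expected)
  expect_error(nni_variants(q, mr_split(c("A", "C"), c("B", "D"))),
               "not an inner split")
  ## RF 2 from the original, always; and both variants differ
  set.seed(141)
  for (rep in 1:20) {
    t <- random_bifurcating(paste0("t", 1:8))
    s <- t$splits[[sample.int(length(t$splits), 1)]]
    v <- nni_variants(t, s)
    expect_identical(rf_distance(t, v[[1]]), 2L)
    expect_identical(rf_distance(t, v[[2]]), 2L)
    expect_identical(rf_distance(v[[1]], v[[2]]), 2L)
    expect_true(is_bifurcating(v[[1]]) && is_bifurcating(v[[2]]))
  }
})

test_that("nni_sweep is monotone and returns equal-scoring trees", {
  set.seed(151)
  model <- random_bifurcating(paste0("t", 1:8))
  inputs <- lapply(1:3, function(i) restrict_tree(model, sample(model$taxa, 6)))
  start <- random_bifurcating(model$taxa)
  s0 <- total_score(start, inputs, "minus")
  res <- nni_sweep(start, inputs, "minus", seed = 3)
  expect_lte(res$score, s0)
  for (t in res$trees)
    expect_identical(total_score(t, inputs, "minus"), res$score)
  ## an isolated optimum sweeps to itself
  res2 <- nni_sweep(model, list(model), "minus")
  expect_identical(res2$score, 0L)
  expect_true(any(vapply(res2$trees, same_tree, logical(1), t2 = model)))
})

test_that("tdr_step keeps the taxon set and is seed-deterministic", {
  set.seed(161)
  model <- random_bifurcating(paste0("t", 1:12))
  inputs <- lapply(1:4, function(i) restrict_tree(model, sample(model$taxa, 9)))
  t <- stepwise_addition_tree(inputs, "minus", seed = 1)
  a <- tdr_step(t, inputs, "minus", 0.25, seed = 9)
  b <- tdr_step(t, inputs, "minus", 0.25, seed = 9)
  expect_true(same_tree(a, b))
  expect_identical(a$taxa, t$taxa)
  expect_true(is_bifurcating(a))
})

test_that("run_search matches the exhaustive optimum on small instances", {
  set.seed(171)
  methods <- c("minus", "plus", "plusg")
  for (rep in 1:6) {
    taxa <- paste0("t", 1:7)
    inputs <- lapply(1:3, function(i) random_bifurcating(sample(taxa, 6)))
    m <- methods[(rep - 1) %% 3 + 1]
    ex <- suppressWarnings(exhaustive_supertree(inputs, m))
    res <- run_search(inputs, search_config(method = m, seed = 200 + rep))
    expect_identical(res$best_score, ex$best_score)
    ## all heuristic optima are true optima
    exk <- vapply(ex$optimal_trees, mrsupertree:::tree_key, character(1))
    for (t in res$optimal_trees)
      expect_true(mrsupertree:::tree_key(t) %in% exk)
  }
})

test_that("run_search result contract: rescoring, determinism, monotone", {
  set.seed(181)
  model <- random_bifurcating(paste0("t", 1:12))
  inputs <- lapply(1:5, function(i) restrict_tree(model, sample(model$taxa, 8)))
  r1 <- run_search(inputs, search_config(method = "minus", seed = 77))
  r2 <- run_search(inputs, search_config(method = "minus", seed = 77))
  expect_identical(r1$best_score, r2$best_score)
  expect_same_tree_set(r1$optimal_trees, r2$optimal_trees)
  ## independent recomputation through the relationship-matrix route
  for (t in r1$optimal_trees) {
    expect_true(is_bifurcating(t))
    expect_identical(t$taxa, sort(model$taxa))
    expect_identical(total_score(t, inputs, "minus"), r1$best_score)
  }
  ## the C++-side consensus agrees with the R-side strict consensus
  expect_identical(r1$n_optimal, length(r1$optimal_trees))
  expect_true(same_tree(r1$strict_consensus,
                        strict_consensus(r1$optimal_trees)))
})

test_that("user starting tree is honored", {
  set.seed(191)
  model <- random_bifurcating(paste0("t", 1:10))
  inputs <- lapply(1:4, function(i) restrict_tree(model, sample(model$taxa, 7)))
  res <- run_search(inputs, search_config(method = "minus", seed = 3,
                                          starting_tree = model))
  expect_identical(res$best_score, 0L)
  keys <- vapply(res$optimal_trees, mrsupertree:::tree_key, character(1))
  expect_true(mrsupertree:::tree_key(model) %in% keys)
})
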