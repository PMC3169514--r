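test_that("yule_tree: validity, determinism, quartet coverage", {
  set.seed(251)
  t <- yule_tree(16)
  expect_true(is_bifurcating(t))
  expect_identical(n_taxa(t), 16L)
  set.seed(5); a <- yule_tree(10)
  set.seed(5); b <- yule_tree(10)
  expect_true(same_tree(a, b))
  ## n = 4: all three quartet topologies are reachable
  seen <- character(0)
  for (i in 1:60) seen <- union(seen, mrsupertree:::tree_key(yule_tree(4)))
  expect_length(seen, 3)
})

test_that("yule_tree shape frequencies match the branching process at n = 6", {
  ## independent oracle: enumerate every splitting path of the pure-birth
  ## process (uniform lineage choice) with exact probabilities, classify
  ## the resulting unrooted shape by its cherry count
  paths <- list(list(p = 1, tree = list("l1", "l2")))
  nextleaf <- 3
  for (step in 1:4) {
    nxt <- list()
    for (pa in paths) {
      leaves <- rapply(pa$tree, function(x) x, how = "unlist")
      for (lf in leaves) {
        split_leaf <- function(node) {
          if (is.character(node) && length(node) == 1L)
            return(if (node == lf)
              list(node, paste0("l", nextleaf)) else node)
          lapply(node, split_leaf)
        }
        nxt[[length(nxt) + 1L]] <- list(p = pa$p / length(leaves),
                                        tree = split_leaf(pa$tree))
      }
    }
    paths <- nxt
    nextleaf <- nextleaf + 1
  }
  to_newick <- function(node) {
    if (is.character(node)) return(node)
    paste0("(", paste(vapply(node, to_newick, character(1)), collapse = ","), ")")
  }
  n_cherries <- function(t) {
    sum(vapply(t$splits, function(s)
      min(length(s$left), length(s$right)) == 2L, logical(1)))
  }
  p_snowflake <- 0
  for (pa in paths) {
    t <- parse_newick(paste0(to_newick(pa$tree), ";"))
    if (n_cherries(t) == 3L) p_snowflake <- p_snowflake + pa$p
  }
  ## Monte-Carlo draw from the generator
  set.seed(261)
  N <- 3000
  hits <- 0
  for (i in seq_len(N)) if (n_cherries(yule_tree(6)) == 3L) hits <- hits + 1
  se <- sqrt(p_snowflake * (1 - p_snowflake) / N)
  expect_lt(abs(hits / N - p_snowflake), 4 * se + 1e-9)
})

test_that("make_inputs: coverage, display, degenerate handling", {
  set.seed(271)
  model <- yule_tree(12)
  ## p_delete = 0: k copies of the model
  ins0 <- make_inputs(model, 3, 0)
  for (t in ins0) expect_true(same_tree(t, model))
  for (rep in 1:10) {
    ins <- make_inputs(model, 5, 0.4)
    expect_identical(sort(unique(unlist(lapply(ins, function(t) t$taxa)))),
                     model$taxa)
    for (t in ins) {
      expect_gte(n_taxa(t), 4L)
      expect_true(same_tree(t, restrict_tree(model, t$taxa)))
    }
  }
  expect_error(make_inputs(model, 2, 0.95, max_attempts = 5), "attempts")
})

test_that("nni_perturb: identity, forced swap, RF bound", {
  set.seed(281)
  t <- yule_tree(10)
  expect_true(same_tree(nni_perturb(t, 0), t))
  ## forced swap on the quartet gives one of the two alternatives
  q <- mr_tree(c("A", "B", "C", "D"), list(mr_split(c("A", "B"), c("C", "D"))))
  seen <- character(0)
  for (i in 1:40) {
    p <- nni_perturb(q, 1)
    expect_identical(rf_distance(p, q), 2L)
    seen <- union(seen, mrsupertree:::tree_key(p))
  }
  expect_length(seen, 2)
  ## E[RF] <= 2 p (n - 3), approached for small p
  p_nni <- 0.1; n <- 12
  rfs <- replicate(300, rf_distance(t <- yule_tree(n), nni_perturb(t, p_nni)))
  bound <- 2 * p_nni * (n - 3)
  expect_lte(mean(rfs), bound + 1e-9)
  expect_gte(mean(rfs), 0.6 * bound)
})

test_that("evaluate_reconstruction metrics", {
  set.seed(291)
  model <- yule_tree(10)
  ev <- evaluate_reconstruction(model, model, 0L)
  expect_identical(ev$rf_norm, 0)
  expect_true(ev$success)
  star <- mr_tree(model$taxa)
  ev2 <- evaluate_reconstruction(star, model, 0L)
  expect_identical(ev2$missing_frac, 1)
  expect_identical(ev2$incorrect_frac, 0)
  ## one collapsed split
  part <- mr_tree(model$taxa, model$splits[-1], validate = FALSE)
  ev3 <- evaluate_reconstruction(part, model, 0L)
  expect_equal(ev3$missing_frac, 1 / (n_taxa(model) - 3))
  expect_equal(ev3$rf_norm, 1 / (2 * n_taxa(model) - 6))
  ## missing + incorrect recompose the RF against a bifurcating model
  sup <- yule_tree(10, labels = model$taxa)
  ev4 <- evaluate_reconstruction(sup, model, 0L)
  expect_equal((ev4$missing_frac + ev4$incorrect_frac) * (10 - 3),
               rf_distance(sup, model))
  expect_error(evaluate_reconstruction(yule_tree(8), model), "taxon set")
})

test_that("run_experiment: compatible setting succeeds and is reproducible", {
  cfg <- sim_config(n_taxa = 12, n_input_trees = 5, p_delete = 0.3,
                    replicates = 3, seed = 42, method = "minus")
  e1 <- run_experiment(cfg)
  e2 <- run_experiment(cfg)
  expect_identical(e1$table, e2$table)
  expect_identical(e1$summary$success_rate, 1)
  expect_true(all(e1$table$best_score == 0L))
  ## every compatible replicate admits score 0 by construction
  expect_true(all(e1$table$n_inner_splits <= 12 - 3))
  ## the three methods return the same number of optimal trees on shared
  ## seeds in the compatible setting
  for (m in c("plus", "plusg")) {
    em <- run_experiment(sim_config(n_taxa = 12, n_input_trees = 5,
                                    p_delete = 0.3, replicates = 3,
                                    seed = 42, method = m))
    expect_identical(em$table$n_optimal_trees, e1$table$n_optimal_trees)
    expect_identical(em$table$best_score, e1$table$best_score)
  }
})

test_that("experiment tables round-trip through TSV", {
  cfg <- sim_config(n_taxa = 8, n_input_trees = 3, p_delete = 0.2,
                    replicates = 2, seed = 7)
  e <- run_experiment(cfg)
  f <- tempfile(fileext = ".tsv")
  write_experiment(e, f)
  back <- utils::read.delim(f)
  expect_identical(nrow(back), 2L)
  expect_identical(back$n_inner_splits, e$table$n_inner_splits)
  expect_true(file.exists(sub("\\.tsv$", ".json", f)))
})
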