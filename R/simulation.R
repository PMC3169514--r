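## Simulation study pipeline: Yule model trees, input-tree generation by
## taxon deletion and NNI perturbation, supertree reconstruction, and the
## evaluation metrics (normalized RF, missing/incorrect split fractions).

#' Simulate a Yule (pure-birth) tree topology
#'
#' Starting from two lineages, a uniformly chosen extant lineage is split
#' until `n` tips exist; branch lengths are never generated because all
#' downstream computation is topological.  Taxon labels are assigned to
#' tips in random order.
#'
#' @param n number of taxa (at least 4).
#' @param labels optional taxon labels (default `t01 ... tn`).
#' @return an unrooted bifurcating `mr_tree`.
#' @export
yule_tree <- function(n, labels = NULL) {
  stopifnot(n >= 4)
  if (is.null(labels))
    labels <- sprintf("t%0*d", nchar(as.character(n)), seq_len(n))
  stopifnot(length(labels) == n)
  ## children[[i]]: the two children of internal node i (negative = tip id)
  children <- list(c(-1L, -2L))
  tips <- c(-1L, -2L)          # extant lineages, as (negative tip id) refs
  where <- c(1L, 1L)           # index of the internal node holding each tip
  slot <- c(1L, 2L)
  ntip <- 2L
  while (ntip < n) {
    i <- sample.int(ntip, 1L)
    ## split tip i: replace it by a new internal node with two fresh tips
    newnode <- length(children) + 1L
    a <- -(ntip + 1L)
    children[[where[i]]][slot[i]] <- newnode
    children[[newnode]] <- c(tips[i], a)
    where[i] <- newnode; slot[i] <- 1L
    tips <- c(tips, a); where <- c(where, newnode); slot <- c(slot, 2L)
    ntip <- ntip + 1L
  }
  lab <- sample(labels)        # exchangeable labeling
  render <- function(node) {
    parts <- vapply(children[[node]], function(ch)
      if (ch < 0L) lab[-ch] else render(ch), character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  parse_newick(paste0(render(1L), ";"))
}

#' Generate overlapping input trees by random taxon deletion
#'
#' Each of `k` input trees is the model tree restricted to a uniform
#' random subset of the taxa: exactly `round(p_delete * n)` taxa are
#' deleted from every tree (the deletion fraction is fixed per tree;
#' never more than `n - 4`).  The whole dataset is resampled until every
#' taxon survives in at least one tree.
#'
#' @param model bifurcating `mr_tree`.
#' @param k number of input trees.
#' @param p_delete fraction of taxa deleted from each input tree.
#' @param max_attempts resampling cap for degenerate settings.
#' @return list of `mr_tree` (restrictions of the model).
#' @export
make_inputs <- function(model, k, p_delete, max_attempts = 1e4) {
  stopifnot(is_bifurcating(model), k >= 1, p_delete >= 0, p_delete < 1)
  n <- n_taxa(model)
  n_del <- min(round(p_delete * n), n - 4L)
  for (a in seq_len(max_attempts)) {
    keep <- t(replicate(k, {
      z <- rep(TRUE, n); z[sample.int(n, n_del)] <- FALSE; z
    }))
    if (!all(colSums(keep) >= 1L)) next
    return(lapply(seq_len(k), function(i)
      restrict_tree(model, model$taxa[keep[i, ]])))
  }
  stop("could not generate a valid dataset in ", max_attempts, " attempts")
}

#' Perturb a tree by random NNI moves
#'
#' The inner splits of the original tree are visited in random order; each
#' undergoes an NNI with probability `p_nni`, the two alternatives being
#' equally likely.  Splits created by earlier swaps are never re-perturbed.
#'
#' @param t bifurcating `mr_tree`.
#' @param p_nni per-inner-edge NNI probability.
#' @return a bifurcating `mr_tree` on the same taxa.
#' @export
nni_perturb <- function(t, p_nni) {
  stopifnot(is_bifurcating(t), p_nni >= 0, p_nni <= 1)
  if (length(t$splits) == 0L || p_nni == 0) return(t)
  todo <- sample(t$splits)
  cur <- t
  for (s in todo) {
    if (stats::runif(1) >= p_nni) next
    v <- nni_variants(cur, s)
    cur <- v[[sample.int(2L, 1L)]]
  }
  cur
}

#' Evaluate a reconstructed supertree against the model tree
#'
#' @param supertree reconstructed `mr_tree` (possibly multifurcating).
#' @param model bifurcating `mr_tree` on the same taxa.
#' @param best_score the search's best score (0 required for success).
#' @return list with `rf_norm` (RF / (2n-6)), `missing_frac` (model splits
#'   absent from the supertree, / (n-3)), `incorrect_frac` (supertree
#'   splits absent from the model, / (n-3)), and `success` (score 0 and no
#'   incorrect splits).
#' @export
evaluate_reconstruction <- function(supertree, model, best_score = NA) {
  if (!identical(supertree$taxa, model$taxa))
    stop("supertree and model tree must share their taxon set")
  n <- n_taxa(model)
  ks <- tree_split_keys(supertree)
  km <- tree_split_keys(model)
  missing <- sum(!(km %in% ks))
  incorrect <- sum(!(ks %in% km))
  list(rf_norm = (missing + incorrect) / (2 * n - 6),
       missing_frac = missing / (n - 3),
       incorrect_frac = incorrect / (n - 3),
       success = identical(as.integer(best_score), 0L) && incorrect == 0L)
}

#' Simulation configuration
#'
#' Defaults mirror the published study: 10 input trees, deletion fraction
#' 0.25 or 0.5, NNI perturbation probability 0 (compatible
#' inputs), 0.1 or 0.2.
#'
#' @param n_taxa taxa in the model tree (32 or 64 in the study).
#' @param n_input_trees input trees per replicate.
#' @param p_delete fraction of taxa deleted from each input tree.
#' @param p_nni per-inner-edge NNI perturbation probability.
#' @param replicates number of replicates.
#' @param seed RNG seed.
#' @param method see [mr_method()].
#' @param contract apply the contraction step.
#' @param max_trees cap on collected equal-scoring trees.
#' @export
sim_config <- function(n_taxa = 32, n_input_trees = 10, p_delete = 0.25,
                       p_nni = 0, replicates = 100, seed = 1,
                       method = "minus", contract = TRUE, max_trees = 1e5) {
  stopifnot(n_taxa >= 4, n_input_trees >= 1,
            p_delete >= 0, p_delete < 1, p_nni >= 0, p_nni <= 1,
            replicates >= 1)
  structure(list(n_taxa = n_taxa, n_input_trees = n_input_trees,
                 p_delete = p_delete, p_nni = p_nni,
                 replicates = replicates, seed = as.integer(seed),
                 method = mr_method(method), contract = isTRUE(contract),
                 max_trees = max_trees),
            class = "mr_sim_config")
}

#' Run the simulation experiment
#'
#' Per replicate: Yule model tree, taxon-deleted (and optionally
#' NNI-perturbed) input trees, MR supertree reconstruction, evaluation.
#'
#' @param config an [sim_config()].
#' @param progress print one line per replicate.
#' @return list with `table` (one row per replicate), `summary` (means),
#'   and `config`.
#' @export
run_experiment <- function(config = sim_config(), progress = FALSE) {
  stopifnot(inherits(config, "mr_sim_config"))
  rows <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed(((config$seed %% 2100000L) * 1009L + r) %% 2147483629L)
    model <- yule_tree(config$n_taxa)
    inputs <- make_inputs(model, config$n_input_trees, config$p_delete)
    if (config$p_nni > 0)
      inputs <- lapply(inputs, nni_perturb, p_nni = config$p_nni)
    res <- mr_supertree(inputs,
                        search_config(method = config$method,
                                      contract = config$contract,
                                      max_trees = config$max_trees))
    cons <- res$search$strict_consensus
    ev <- evaluate_reconstruction(res$supertree, model,
                                  res$search$best_score)
    rows[[r]] <- data.frame(
      replicate = r,
      best_score = res$search$best_score,
      n_optimal_trees = res$search$n_optimal,
      n_inner_splits = length(cons$splits),
      n_inner_splits_final = length(res$supertree$splits),
      rf_norm = ev$rf_norm,
      missing_frac = ev$missing_frac,
      incorrect_frac = ev$incorrect_frac,
      success = ev$success)
    if (progress)
      message(sprintf("replicate %d: score %d, %d optimal, %d splits",
                      r, res$search$best_score,
                      res$search$n_optimal,
                      length(cons$splits)))
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = list(success_rate = mean(tab$success),
                      mean_inner_splits = mean(tab$n_inner_splits),
                      mean_optimal_trees = mean(tab$n_optimal_trees),
                      mean_rf_norm = mean(tab$rf_norm),
                      mean_missing_frac = mean(tab$missing_frac),
                      mean_incorrect_frac = mean(tab$incorrect_frac)),
       config = config)
}

#' Write an experiment table as TSV with a JSON config sidecar
#'
#' @param experiment result of [run_experiment()].
#' @param file path of the TSV; the sidecar gets extension `.json`.
#' @export
write_experiment <- function(experiment, file) {
  utils::write.table(experiment$table, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sidecar <- paste0(sub("\\.tsv$", "", file), ".json")
  writeLines(jsonlite::toJSON(unclass(experiment$config), auto_unbox = TRUE),
             sidecar)
  invisible(file)
}
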