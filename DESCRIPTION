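Package: mrsupertree
Title: Majority-Rule Supertrees from Overlapping Phylogenetic Trees
Version: 0.1.0
Authors@R: person("mrsupertree", "developers", role = c("aut", "cre"),
    email = "mrsupertree@example.org")
Description: Split-based computation of majority-rule (MR) supertrees from
    overlapping unrooted input trees.  Provides exact closed-form scores for
    the MR(-), MR(+) and MR(+)g variants on bifurcating trees via a
    relationship matrix of split relations (subsplit, compatible,
    incompatible), a two-stage heuristic tree search (step-wise addition,
    nearest-neighbor interchange, taxa-deletion-reinsertion) returning all
    best-scoring bifurcating supertrees, strict-consensus and
    majority-contraction post-processing with x/y support labels,
    brute-force oracles certifying the score formulas on small instances,
    and a Yule-tree simulation pipeline for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
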