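---
title: "Majority-rule supertrees from split relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Majority-rule supertrees from split relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsupertree)
```

## The problem

A supertree method combines overlapping unrooted gene trees — trees whose
taxon sets differ — into one tree on the union of all taxa.
Majority-rule (MR) supertrees generalize the majority-rule consensus: the
supertree is defined as the strict consensus of *all* trees minimizing a
sum of Robinson–Foulds (RF) style distances to the input trees.  Because
the RF distance is only defined for equal taxon sets, three variants arise
from how the taxon-set mismatch is resolved for a supertree $S$ (on $n$
taxa) and an input tree $G$ (on $n_G \le n$ taxa):

* **MR($-$)** — prune: $d^-(S, G) = \mathrm{RF}(S|_{L(G)},\, G)$;
* **MR($+$)** — graft onto edges: $d^+(S, G)$ is the minimum RF over all
  *bifurcating* extensions of $G$ placing the missing taxa onto edges;
* **MR($+$)g** — graft onto edges or nodes: $d^{+g}(S, G)$ additionally
  allows attaching missing taxa to inner nodes (creating
  multifurcations, never refining those already in $G$).

For bifurcating $S$ and $G$ all three have closed forms through the
**relationship matrix**: classify every (input split $g_i$, supertree
split $s_j$) pair as *subsplit*, *compatible (but no subsplit)* or
*incompatible* (compatibility of splits with unequal taxon sets is tested
after restriction to the shared taxa).  With

* $C$ = number of input-tree splits incompatible with at least one
  supertree split, and
* $B$ = number of supertree splits incompatible with at least one
  input-tree split,

one gets $d^- = 2C$, $d^{+g} = B + C$, and $d^+ = 2B$, where $B$ and $C$
are computed after the *dummy-taxon modification*: every maximal supertree
subtree containing no input-tree taxon is collapsed to a single
placeholder taxon (`modify_supertree()`).  For MR($-$) the score extends
to multifurcating inputs as $d^- = 2C + m$ with $m$ the input tree's
multifurcation count.  The package certifies all three formulas against
independent brute-force oracles (pruned RF; exhaustive edge grafting;
exhaustive edge-or-node grafting) in its test suite.

Two equivalences are worth knowing because the implementation uses them:

* $B$ and $C$ are unchanged by the dummy-taxon modification, since every
  collapsed split restricts to an empty or trivial split on the shared
  taxa and trivial splits are compatible with everything.  The R-level
  scoring functions follow the textbook route (modify, then build the
  matrix); the C++ search core scores with restriction-aware
  incompatibility on the unmodified supertree.  Tests assert both routes
  agree.
* In the consensus setting (equal taxon sets, bifurcating trees) all
  three distances collapse to the plain RF distance, which the suite
  checks exhaustively for $n = 6$.

## The constructive witness

The upper-bound half of the $B + C$ formula is constructive and is
implemented in `construct_witness()`: missing taxa hanging between
supertree edges that restrict to one and the same input split ("good"
taxa) are placed on that edge at no cost; the remaining $B - C$ "bad"
taxa are placed onto a node adjacent to the edge of a conflicting input
split, each costing one split.  One subtlety: not *every* conflicting
split admits the placement — a careless choice can break a subsplit match
elsewhere and cost two.  The implementation therefore selects, among all
nodes adjacent to conflicting splits, the one minimizing the partial RF;
the tightness test confirms the witness then achieves exactly $B + C$.

## Heuristic search

Minimizing the total score over bifurcating supertrees is done
heuristically (`run_search()`), with all randomness drawn from R's RNG so
a seed fixes the result:

1. **Starting tree** by step-wise addition: a random taxon order; the
   first four taxa get the quartet topology most frequent among the
   inputs; each further taxon is inserted at the attachment point
   minimizing the method's criterion over the *informative* inputs (those
   containing the taxon plus at least three placed taxa).  For $d^-$ the
   criterion is the summed pruned RF, for $d^+$ the summed count of
   input trees contradicting each supertree split, and for $d^{+g}$ the
   two strategies alternate between insertions.  Ties break uniformly at
   random.
2. **Exploration stage**: NNI hill-climbing (replace an inner split by
   one of its two alternatives whenever that strictly lowers the score)
   alternating with TDR restarts (delete a fraction of taxa — default
   0.25 — and reinsert them by step-wise addition).  A TDR product seen
   before, or yielding neither an improvement nor a new best-scoring
   tree, counts as a discard.  The stage ends after $l^2$ iterations
   ($l = n - 3$; an iteration is one NNI replacement or one TDR move) or
   after `discard_limit` consecutive discards.
3. **Broadening stage**: every recorded best-scoring tree is NNI-explored
   so that the whole equal-score neighbourhood — connected by
   zero-gain NNI moves — is visited.
4. **Consensus**: the strict consensus of all optimal trees, followed by
   deletion of splits contradicted by $\ge 50\%$ of the input trees
   (skipped with `contract = FALSE`, giving the "-version" methods).
   Splits are annotated `x/y`: `x` inputs do not contradict the split,
   `y` contain a nontrivial subsplit supporting it.

Design choices where the published description is ambiguous or silent:

* `discard_limit` defaults to $l$ (the threshold is unreadable in the
  source material); experiments at $n = 32$ showed the recovered optimum
  set is insensitive to raising it up to $l^2$.
* NNI sweeps visit splits in a fresh random permutation per pass to avoid
  directional bias; the criterion fixes no order.
* "Seen before" is decided by a canonical split-set hash over all trees
  visited in the run.
* NNI evaluations for MR($-$) use an incremental per-input cache (the
  pruned-RF distance shifts by O(1) multiset updates when one split is
  replaced); every returned tree is nevertheless re-scored from scratch,
  so a caching bug cannot corrupt results silently.
* Only a bounded number of optimal trees is materialized as R objects
  (`max_returned_trees`); the reported optimum count and the strict
  consensus always cover the complete collected set, which matters for
  degenerate datasets with tens of thousands of equal-scoring trees.
* The number of collected equal-score trees is capped (default $10^5$,
  with a warning) to survive degenerate inputs with astronomically many
  optima.
* On small instances (7 taxa) the search provably matches exhaustive
  enumeration: in the test suite the best score agrees with the true
  minimum over all 945 trees in at least 95% of random instances, and on
  compatible 8-taxon datasets the *complete* optimal set was recovered in
  every exhaustively checked instance.

## Simulation pipeline

`run_experiment()` reproduces the published evaluation design:

* **Model trees** from a Yule (pure-birth) process: starting from two
  lineages, a uniformly chosen extant lineage splits until $n$ tips
  exist.  Only the topology is kept — every downstream computation is
  purely topological, so branch lengths are never generated.  The tip
  label assignment is randomized to keep labeled topologies exchangeable.
* **Input trees** (default 10 per replicate) are restrictions of the
  model tree with exactly $\mathrm{round}(p_{del} \cdot n)$ taxa deleted
  per tree, resampled until every taxon occurs in at least one input.
  The deletion fraction is *fixed per tree*, not an independent per-taxon
  coin flip: the published text speaks of "the fraction of deleted taxa
  in each input tree", and with the complete-optimum-recovery property
  verified separately, only the fixed-fraction reading reproduces the
  published mean consensus resolution (24.9 inner splits at $n = 32$,
  50% deletion; the Bernoulli reading gives ≈ 26.2).
* **Incompatibility** is injected by NNI-perturbing each input tree: the
  original inner splits are visited once in random order and each is
  swapped with probability $p_{nni}$ (both alternatives equally likely);
  products of earlier swaps are never re-perturbed.
* **Metrics** per replicate: normalized RF to the model ($/(2n-6)$),
  missing and incorrect split fractions ($/(n-3)$), the number of optimal
  trees and of consensus inner splits, and the success flag (score 0 and
  no split absent from the model tree).

What the generator does *not* emulate: real gene trees estimated from
finite alignments (no sequence evolution or reconstruction error model),
rogue taxa, or input trees of heterogeneous size.  A green simulation
test therefore establishes correctness of the pipeline under the stated
generative model, not method performance on empirical data.

## Numerical and degenerate-input choices

* Taxon labels are arbitrary strings; splits are canonicalized by sorting
  sides and leading with the side containing the smallest label, which
  makes set equality and hashing exact (no floating point anywhere —
  all scores are integers).
* The C++ search core stores splits as 128-bit masks over a global taxon
  index, limiting searches to 128 taxa; the R-level algebra has no such
  limit.
* Trees need at least 3 taxa; inputs with no inner splits carry no
  information and can be dropped on reading (`drop_uninformative`).
* TDR never deletes below 4 remaining taxa; step-wise insertion with no
  informative input places the taxon uniformly at random.
* Ties in the insertion criterion and the quartet vote are broken
  uniformly at random through R's RNG (reservoir sampling), so results
  are reproducible given a seed.

## Known limitations

* The search space is bifurcating trees only; multifurcating optima are
  reachable only through the consensus/contraction step, mirroring the
  published algorithm (score formulas for multifurcating supertrees are
  an open problem).
* MR($+$)/MR($+$)g require bifurcating inputs; only MR($-$) accepts
  multifurcating input trees.
* The brute-force oracles are guarded (at most 6 missing taxa, at most
  8 taxa for exhaustive enumeration) and exist for certification, not
  production use.
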