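# mrsupertree

Split-based computation of **majority-rule (MR) supertrees**: combining
overlapping unrooted phylogenetic trees (e.g. gene trees with different
taxon samples) into a supertree on the union of all taxa, together with
the simulation machinery to evaluate the methods.

## The methods

For a bifurcating supertree *S* and input tree *G*, three
Robinson–Foulds-style distances handle the taxon-set mismatch:

| method  | idea                                   | closed form |
|---------|----------------------------------------|-------------|
| MR(−)   | prune *S* to *G*'s taxa                | d⁻ = 2C (+ m for multifurcating *G*) |
| MR(+)g  | best edge-or-node extension of *G*     | d⁺g = B + C |
| MR(+)   | best bifurcating edge extension of *G* | d⁺ = 2B     |

*C* counts input splits incompatible with ≥ 1 supertree split, *B*
counts supertree splits incompatible with ≥ 1 input split; both are read
off a **relationship matrix** classifying every split pair as subsplit /
compatible / incompatible, after collapsing supertree subtrees without
input taxa to a dummy taxon (`modify_supertree()`).  The MR supertree is
the strict consensus of **all** bifurcating trees minimizing the summed
distance, with majority-contradicted splits contracted afterwards.  A
two-stage heuristic (step-wise addition starting tree; NNI hill climbs
alternating with taxa-deletion-reinsertion restarts; an exhaustive NNI
sweep of the equal-score neighbourhood) searches for the full optimal
set.  Brute-force oracles (prune-and-RF, exhaustive grafting, exhaustive
tree enumeration) certify the closed forms and the search on small
instances.

## Worked example

The bundled 8-taxon supertree `((A,B),C,(D,(E,(F,(G,H)))));` against the
5-taxon input tree `((D,F),(C,(G,H)));`:

```r
library(mrsupertree)
inp <- system.file("extdata", "worked_example_input.nwk", package = "mrsupertree")
sup <- system.file("extdata", "worked_example_supertree.nwk", package = "mrsupertree")
cmd_score(inp, sup, "minus")
#> tree 1: d = 2
#> total score (minus): 2

S <- read_newick(sup)[[1]]; G <- read_newick(inp)[[1]]
conflict_counts(build_relationship_matrix(G, modify_supertree(S, G$taxa)))
#> C B
#> 1 2
```

So d⁻ = 2C = 2 (two splits change when the pruned supertree is compared
with the input tree), d⁺g = B + C = 3 and d⁺ = 2B = 4 — the costs of the
best extensions of the input tree onto the supertree's taxa.

A full reconstruction from simulated overlapping inputs:

```r
set.seed(7)
model  <- yule_tree(12)                      # 12-taxon model topology
inputs <- make_inputs(model, 5, 0.25)        # 5 trees, 25% taxa deleted each
res <- mr_supertree(inputs, search_config(method = "minus", seed = 42))
res
#> MR supertree: score 0, 1 optimal tree(s), 9 inner split(s)
#> ((t04,t05)5/2,(((t08,t10)5/2,(((t07,t11)5/2,((t09,t12)5/4,t06)5/4)5/5,t03)5/5)5/5,t02)5/5,t01);
```

Score 0 means every input tree is displayed exactly; the `x/y` node
labels say how many of the 5 inputs do not contradict (x) and actively
support (y) each split.

## Command line

```sh
exec/mrst score     --trees inputs.nwk --supertree super.nwk --method minus
exec/mrst supertree --trees inputs.nwk --out run1 --method minus --seed 1 [--no-contract] [--oracle]
exec/mrst simulate  --config sim.json --out sim.tsv
```

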