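# gtcorrect

Fast error correction of gene trees by SPR and TBR rearrangement against a
species tree.

## The problem

Gene trees estimated from single-gene alignments are noisy, and when a
noisy gene tree *G* is reconciled with a species tree *S*, estimation error
masquerades as evolutionary events: spurious duplications, losses, and
deep-coalescence (incomplete lineage sorting) episodes. A standard remedy
is *error correction by local rearrangement*: assume the true gene tree
lies within one edit of the estimated one, and replace *G* by the tree in
its SPR (subtree prune and regraft) or TBR (tree bisection and
reconnection) neighborhood that minimizes the reconciliation cost.

Reconciliation uses the LCA mapping ℳ : V(G) → V(S), which sends each gene
vertex to the most recent species vertex that could contain it (for a
leaf, the species carrying its label; for an internal vertex, the least
common ancestor of its children's images). With dp(·) the species-tree
depth, the per-vertex costs for an internal g with children h₁, h₂ are

* **dup** — 1 if ℳ(g) ∈ {ℳ(h₁), ℳ(h₂)}, else 0;
* **duploss** — the duplication indicator plus the loss count
  Σᵢ |dp(ℳ(hᵢ)) − dp(ℳ(g)) − 1| (0 when both children map with g);
* **deepcoal** — Σᵢ (dp(ℳ(hᵢ)) − dp(ℳ(g))), with |E(S)| subtracted from
  the tree-wide total.

Costs are summed over internal vertices of *G*; all three vanish exactly
when a one-copy *G* is congruent with *S*. Before any computation the
species tree is restricted to the species sampled in the gene tree, so
under-sampled families are handled cleanly.

Scoring each of the Θ(n²) SPR neighbors from scratch costs Θ(n³) per gene
tree (Θ(n⁴) for TBR). This package implements the quadratic alternative:
for a fixed pruned subtree, the restricted neighborhood is organized as a
rooted binary tree whose edges are single NNI moves sliding the
attachment point; along each such edge only two vertices change their LCA
mapping, so the cost difference is updated in constant time and the whole
restricted problem costs Θ(n). A TBR move factors into an optimal
rerooting of the pruned subtree (found by an analogous constant-time
root-sliding scan) followed by an optimal regraft, so the TBR search has
the same quadratic cost as the SPR search. A naive full-recompute oracle
is included and the fast solvers are tested against it exhaustively.

Who is this for: anyone running gene-tree parsimony or reconciliation
analyses (duplication counting, species-tree inference from gene
families, ILS quantification) who needs a fast, deterministic,
assumption-free cleanup pass over thousands of gene trees.

## Worked example

```r
library(gtcorrect)

g <- parse_newick("(((A,C),B),D);")   # estimated gene tree
s <- parse_newick("(((A,B),C),D);")   # accepted species tree

reconciliation_cost(g, s, "dup")       # 1
reconciliation_cost(g, s, "duploss")   # 4
reconciliation_cost(g, s, "deepcoal")  # 1

res <- solve_sec(g, s, "duploss")      # best tree in the SPR neighborhood
res
#> Gene tree correction (spr neighborhood, duploss cost)
#>   cost: 4 -> 0   (24 candidates examined)
#>   edit: SPR prune=4 regraft=6
write_newick(res$best_tree)
#> [1] "((C,(B,A)),D);"
```

The misplaced leaf C implied one duplication and three losses; pruning it
(node 4) and regrafting above B (node 6) restores a tree congruent with
the species tree, at cost 0. `solve_tec()` searches the larger TBR
neighborhood the same way, and `solve_r_sec()` / `solve_r_tec()` expose
the restricted (fixed pruned subtree) problems.

Cohorts are corrected in one call. A built-in generator produces a
synthetic study — by default 8 taxa and 106 one-SPR-corrupted gene trees:

```r
co <- make_cohort(n_taxa = 8, n_genes = 106)
r <- run_correct(co$species, co$genes, model = "deepcoal")
writeLines(r$summary)
#> Error correction: 106 gene trees, deepcoal cost, spr neighborhood, rounds=1
#> Total cost: 406 -> 0
#>
#> cost bin      original corrected
#> 0                    0       106
#> 1                   27         0
#> 2                   20         0
#> 3                   21         0
#> 4                    9         0
#> >4                  29         0
```

Every gene tree carries exactly one random SPR error, and a single
correction pass recovers all 106 to cost 0 — the single-error recovery
property the test suite asserts. The same pipeline is available from the
shell via `exec/gtcorrect` (`correct` and `generate` subcommands).

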