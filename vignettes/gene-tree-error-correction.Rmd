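---
title: "Gene tree error correction by neighborhood search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene tree error correction by neighborhood search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtcorrect)
```

## What the package computes

Given a rooted binary gene tree $G$ and a rooted binary species tree $S$,
`gtcorrect` finds the tree in the SPR or TBR neighborhood of $G$ that
minimizes a reconciliation cost against $S$, under one of three parsimony
models. The premise is that topological error in an estimated gene tree is
usually local, so the "true" tree — or at least a far less misleading one —
lies within a single prune-and-regraft edit. The method is purely
topological and deterministic: no branch lengths, no rates, no model of
sequence evolution.

All costs flow from the LCA mapping $\mathcal{M} : V(G) \to V(S)$. Each
gene leaf maps to the species leaf carrying its label; each internal gene
vertex maps to the least common ancestor of its children's images. For an
internal $g$ with children $h_1, h_2$ and species-tree depth function
$dp$:

* **Duplication (`"dup"`).** $g$ is a duplication iff
  $\mathcal{M}(g) \in \{\mathcal{M}(h_1), \mathcal{M}(h_2)\}$; the cost is
  the number of duplications.
* **Duplication–loss (`"duploss"`).** Adds the loss count
  $\sum_i |dp(\mathcal{M}(h_i)) - dp(\mathcal{M}(g)) - 1|$, taken as 0
  when both children map with $g$ (without that guard a vertex whose two
  children both map with it would spuriously count two losses, and
  congruent trees would not cost 0). The depth-difference form is valid
  because a child's image is never above its parent's image.
* **Deep coalescence (`"deepcoal"`).** The number of species-tree edges
  between a vertex's image and each child's image, summed over internal
  vertices, minus $|E(S)|$. The subtraction makes the count equal "extra
  lineages": each species-tree edge carries one entitled lineage, and
  every additional lineage crossing it is one deep-coalescence event.
  `dc_extra_lineages()` implements that per-edge count literally and the
  test suite checks the two formulations agree on exhaustive 4-leaf
  instances. (An alternative normalization by the internal-vertex count
  $|I(S)|$ appears in some algorithmic statements of the model; only the
  $|E(S)|$ form yields cost 0 for congruent trees, so that is what the
  package implements.)

Costs are exact integers throughout; no floating point enters any scoring
path.

### Incomplete sampling

The leaf-mapping is only well defined when every gene label occurs in the
species tree, and the deep-coalescence normalization assumes every species
is reachable. Real gene families under-sample species, so before any cost
is computed the species tree is restricted to the species present in the
gene tree (`restrict_species_tree()`, applied automatically and reported
as `n_species` in cohort reports). This restores surjectivity of the leaf
mapping and keeps all three costs non-negative, with cost 0 exactly on
(restricted-)congruent one-copy trees. This convention is a package
decision: a fully sampled data set is unaffected by it.

Gene leaf labels either equal species labels or carry a suffix
(`"speciesX|gene1"`); `species_delimiter` selects the prefix before the
first occurrence of the delimiter, which covers the common header styles
without a mapping file.

## The fast search

Scoring one tree costs $\Theta(n)$, and the SPR neighborhood contains
$\Theta(n^2)$ trees, so the naive search is cubic
(`naive_best_in_neighborhood()`, kept deliberately simple as the
correctness oracle). The fast solvers avoid rescoring:

1. **Restricted problem.** Fix the pruned subtree $G_v$. All regraft
   positions form the remaining component $Y$; the solver starts from the
   tree with $G_v$ attached above the root of $Y$ and slides the
   attachment vertex down one edge of $Y$ per step, in preorder with
   backtracking. Each slide is a single NNI. Only the attachment vertex
   and the vertex it displaces change their LCA mapping, so the cost
   delta is the difference of two vertex scores — constant time with a
   constant-time species LCA (`build_lca_index()`, an Euler tour with a
   sparse-table range-minimum structure). One full mapping and scoring
   pass at the start, then $\Theta(1)$ per candidate: $\Theta(n)$ per
   restricted problem, $\Theta(n^2)$ over all $v$ (`solve_sec()`).
2. **Backtracking.** The walk mutates one tree in place. Every descent
   pushes the previous pointers, the two vertex mappings, the two vertex
   scores and the running delta; the matching pop restores them exactly.
   In `verify = TRUE` mode the solver recomputes mapping and score from
   scratch at every traversed edge and asserts (i) the incremental
   mapping is identical to the recomputation, (ii) nothing outside the
   two active vertices moved, (iii) the two-vertex delta equals the full
   score difference, and (iv) the walk ends in exactly its initial state.
   These assertions are run over tens of thousands of edges in the test
   suite.
3. **TBR decomposition.** A TBR move reroots the pruned subtree before
   regrafting. The score contributions of the subtree's internal vertices
   and of the rest of the tree are independent — the subtree root's image
   is the LCA of all its leaf images under every rerooting — so the
   optimum factors into a best rerooting followed by a best regraft.
   `best_rooting()` slides the root across one edge at a time with the
   same two-vertex delta pattern (the root's image never changes; only
   the pivot vertex remaps); an exhaustive rescoring scan is kept behind
   `method = "exhaustive"` as a cross-check. `solve_tec()` therefore has
   the same quadratic complexity as `solve_sec()`.

### The adjacency structure, precisely

The walk relies on the restricted neighborhood forming a rooted binary
tree under attachment slides: the root is the regraft-above-the-root
tree (degree 2: its two slides into the root's children), regrafts above
leaves are leaves of the structure (degree 1: only the slide up), and
regrafts above internal vertices have degree 3 (one slide up, two down).
A subtlety worth recording: if adjacency is instead defined as "any
single NNI transforms one neighbor into the other", the graph acquires
additional chords, because an NNI relocating some *other* subtree can
coincidentally carry one member of the neighborhood onto another. The
structure that matters — and the one the test suite verifies by brute
force on hundreds of small instances — is the one generated by the NNIs
acting on the pruned subtree's attachment edge.

### Tie-breaking and degenerate inputs

* Candidates are examined in a fixed order (pruned vertices in preorder
  of $G$; within one restricted problem, attachment points in preorder of
  the remaining component). The first strict improvement is kept, so
  results are deterministic; when the input tree ties the neighborhood
  minimum the input itself is returned with `edit = NULL` (minimal-change
  bias).
* Gene trees with fewer than 3 leaves admit no topology-changing move and
  are returned unchanged.
* When the pruned vertex is a child of the root, the walk's starting tree
  is isomorphic to $G$ itself; the walk proceeds normally through the
  sibling's subtree.
* Deltas can be negative; all arithmetic is integer.

## The synthetic cohort generator

There is no bundled empirical data; `make_cohort()` /
`corrupt_gene_tree()` generate the study conditions. A species tree grows
by a Yule process (a uniformly chosen leaf splits until `n_taxa` leaves;
topology distribution is irrelevant to correctness testing, so the
simplest standard process is used). A gene tree starts congruent to the
species tree, then, in order: each species leaf is dropped with
probability `drop_leaf_prob` (at least two leaves survive — three when
SPR errors are requested, since a topology-changing SPR needs three);
each surviving leaf becomes a same-label cherry with probability
`dup_leaf_prob` (one clean duplication each: with no SPR errors the
duplication cost equals the cherry count and the deep-coalescence cost is
0); finally `n_spr_errors` uniformly random SPR moves are applied, with
draws that reproduce the current topology rejected, so an "error" always
changes the tree. Generation is a pure, seed-stable function of its
configuration and leaves the caller's RNG stream untouched.

The default cohort — 8 taxa, 106 gene trees, exactly one SPR error each,
no duplicates, no drops — mirrors the shape of a curated single-copy
gene-family study and exercises the headline property: one random SPR
error is always recoverable to cost 0, because the inverse move lies in
the searched neighborhood. What the generator does *not* emulate:
alignment-level estimation noise (errors beyond one edit), birth–death
duplication/loss along the species tree, coalescent variance, or
branch-support information. Passing tests therefore demonstrate
algorithmic correctness (the solvers find true neighborhood minima under
all three models, on multi-copy and under-sampled trees too), not that
one SPR always suffices for real data — on real cohorts the corrected
cost distribution simply shifts downward, and genes whose errors exceed
the neighborhood keep a positive cost.

## Cohort protocol and parameters

`run_correct()` applies one solver pass per gene by default
(`rounds = 1`). More rounds never increase a gene's cost, but unlimited
rearrangement converges every gene tree onto the species tree, erasing
the biological signal reconciliation is meant to read — multi-round mode
exists, and its documentation carries that warning. Summaries bin costs
as 0, 1, 2, 3, 4, >4 for deep coalescence and 0, 1–5, 6–10, 11–15,
16–20, >20 for duplication–loss; the duplication-only model reuses the
latter binning (its costs are bounded by the duplication–loss cost).
`verify = TRUE` re-derives each gene's minimum with the naive oracle and
treats any disagreement as an internal error — a bug trap for the
incremental machinery, intended for small trees only.

Trees are assumed pre-rooted; `root_with` reroots each gene tree on the
edge above a named outgroup leaf first, which is how such cohorts are
usually prepared.

## Problem sizes used by the checks

The shipped suite validates oracle equivalence on 510 seeded random
instances for SPR (species trees of 4–12 leaves, up to two gene copies
per species, all three models) and 510 for TBR (4–10 leaves), verifies
the incremental deltas on over 10⁴ NNI edges in debug mode, checks the
adjacency structure by brute force on 100 instances of up to 8 leaves,
recovery of a single 16-taxon SPR error across 20 replicates and all
models, and a log–log regression of candidates examined against leaf
count over 16–128 leaves (slope within $2 \pm 0.3$, an instrumented count
rather than wall clock). These sizes keep the exhaustive oracles — cubic
and quartic by design — at desk scale while covering every code path;
the fast solvers themselves handle much larger trees, with work bounded
by the quadratic candidate count.

## Known limitations

* Only rooted, fully binary trees: polytomies must be resolved upstream,
  and support values are ignored (no support-weighted rearrangement).
* One edit per pass: errors spanning several intertwined rearrangements
  may not be reachable greedily.
* No lateral gene transfer model, and no probabilistic reconciliation:
  ties among cost-equivalent corrections are broken by traversal order,
  not by likelihood.
* The species tree is taken as known and fixed; the package corrects
  gene trees, it does not search species-tree space (corrected trees can
  of course be fed to any species-tree search tool).
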