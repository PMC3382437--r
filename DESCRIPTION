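Package: gtcorrect
Title: Fast Error Correction of Gene Trees by SPR and TBR Rearrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Error correction of rooted binary gene trees against a known
    species tree by local tree rearrangement. Searches the subtree
    prune-and-regraft (SPR) or tree bisection-and-reconnection (TBR)
    neighborhood of a gene tree for the topology minimizing the
    reconciliation cost under the gene duplication, duplication-loss, or
    deep coalescence parsimony models. The search walks the
    nearest-neighbor-interchange adjacency tree of each restricted SPR
    neighborhood with constant-time incremental updates of the LCA mapping
    and cost, giving quadratic total work per gene tree, and decomposes TBR
    moves into an optimal rerooting of the pruned subtree followed by an
    optimal regraft. Includes naive full-recompute neighborhood oracles for
    verification, a seeded generator of species trees and SPR-perturbed
    multi-copy gene trees, and a cohort-level correction driver with a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
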