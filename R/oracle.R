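# Naive neighborhood baselines: enumerate every SPR/TBR rearrangement and
# score each candidate from scratch. Deliberately simple (cubic/quartic
# time); this is the correctness oracle for the incremental solvers, so it
# shares the edit-operation code but none of the incremental scoring.

#' Exhaustive minimum over an SPR or TBR neighborhood
#'
#' Enumerates the neighborhood explicitly and scores every candidate with a
#' full reconciliation-cost recomputation. The true minimum found here is
#' the reference the fast solvers are tested against.
#'
#' @param g Gene `rbtree` (at least 3 leaves).
#' @param s Species `rbtree`.
#' @param model One of `"dup"`, `"duploss"`, `"deepcoal"`.
#' @param move `"spr"` or `"tbr"`.
#' @param v Node id to prune at, or `NULL` for the whole neighborhood.
#' @param species_delimiter Optional label-resolution delimiter.
#' @param keep_costs If `TRUE` the full integer multiset of candidate costs
#'   is attached as `$costs`.
#' @return A `gt_correction`; the input tree (with `edit = NULL`) when no
#'   candidate beats its cost.
#' @export
naive_best_in_neighborhood <- function(g, s, model, move = c("spr", "tbr"),
                                       v = NULL, species_delimiter = NULL,
                                       keep_costs = FALSE) {
  move <- match.arg(move)
  mid <- model_id(model)
  model <- match.arg(model, COST_MODELS)
  ctx <- species_context(g, s, species_delimiter)
  orig <- recon_cost_ctx(g, ctx, mid)
  vs <- if (is.null(v)) preorder_nodes(g)[-1L] else as.integer(v)
  best_cost <- NA_integer_
  best_tree <- NULL
  best_edit <- NULL
  cand <- 0L
  costs <- if (keep_costs) integer(0) else NULL
  score_one <- function(tr, edit) {
    cost <- recon_cost_ctx(tr, ctx, mid)
    cand <<- cand + 1L
    if (keep_costs) costs[[cand]] <<- cost
    if (is.na(best_cost) || cost < best_cost) {
      best_cost <<- cost; best_tree <<- tr; best_edit <<- edit
    }
  }
  for (vv in vs) {
    ys <- spr_targets(g, vv)
    if (move == "spr") {
      for (y in ys) score_one(spr(g, vv, y), new_edit("SPR", vv, y))
    } else {
      xs <- preorder_nodes(g, vv)
      for (x in xs) for (y in ys)
        score_one(tbr(g, vv, x, y), new_edit("TBR", vv, y, reroot_at = x))
    }
  }
  res <- if (!is.na(best_cost) && best_cost < orig)
    new_correction(best_tree, best_cost, orig, best_edit, cand, model, move)
  else
    new_correction(g, orig, orig, NULL, cand, model, move)
  if (keep_costs) res$costs <- costs
  res
}

#' Deep-coalescence cost as an extra-lineage count
#'
#' Independent formulation of the deep-coalescence cost: each gene-tree
#' edge is traced along the species-tree path between the images of its
#' endpoints, and every species-tree edge contributes the number of gene
#' lineages crossing it minus one. Used as a cross-model check of
#' [reconciliation_cost()] under `"deepcoal"`.
#'
#' @inheritParams reconciliation_cost
#' @return Integer deep-coalescence cost.
#' @export
dc_extra_lineages <- function(g, s, species_delimiter = NULL) {
  ctx <- species_context(g, s, species_delimiter)
  map <- map_gene(g, ctx)
  se <- ctx$s_eff
  cnt <- integer(n_nodes(se))
  for (v in seq_len(n_nodes(g))) {
    p <- g$parent[v]
    if (is.na(p)) next
    a <- map[v]; b <- map[p]
    while (a != b) {          # walk up; counts the edge above each vertex
      cnt[a] <- cnt[a] + 1L
      a <- se$parent[a]
    }
  }
  nodes <- seq_len(n_nodes(se))
  sum(cnt[nodes[nodes != se$root]] - 1L)
}
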