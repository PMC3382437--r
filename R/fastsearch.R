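# Fast SPR/TBR error-correction solvers.
#
# The restricted SPR problem (best regraft of a fixed pruned subtree) is
# solved by walking the NNI-adjacency tree of the restricted neighborhood:
# the walk starts at the tree with the pruned subtree regrafted above the
# root, then slides the attachment vertex down one edge per step. Each step
# is one NNI; only two vertices change their LCA mapping, so the cost
# difference is computed in constant time from those two vertex scores.
# Backtracking restores the previous state exactly (pointers, the two
# mappings, the two scores, and the running delta). Total work is linear
# per restricted problem and quadratic for the full neighborhood.
#
# TBR adds a free rerooting of the pruned subtree; the subtree's score and
# the regraft score are independent, so the best rerooting (found by an
# analogous constant-time root-sliding scan) composed with the best regraft
# is the joint optimum.

new_correction <- function(best_tree, best_cost, original_cost, edit,
                           candidates, model, neighborhood,
                           edges_checked = NA_integer_) {
  structure(list(best_tree = best_tree, best_cost = as.integer(best_cost),
                 original_cost = as.integer(original_cost), edit = edit,
                 candidates_examined = as.integer(candidates),
                 model = model, neighborhood = neighborhood,
                 edges_checked = as.integer(edges_checked)),
            class = "gt_correction")
}

#' @export
print.gt_correction <- function(x, ...) {
  cat(sprintf("Gene tree correction (%s neighborhood, %s cost)\n",
              x$neighborhood, x$model))
  cat(sprintf("  cost: %d -> %d   (%d candidates examined)\n",
              x$original_cost, x$best_cost, x$candidates_examined))
  cat("  edit:", if (is.null(x$edit)) "none" else format(x$edit), "\n")
  invisible(x)
}

# Root vertex of the NNI-adjacency tree: the pruned subtree regrafted at
# the root of the remaining component (the planted-root position).
build_gbar <- function(g, v) {
  u <- g$parent[v]
  y <- if (is.na(g$parent[u])) sibling_of(g, v) else g$root
  spr(g, v, y)
}

# Core restricted-SPR walk. Returns the raw (un-normalized) best score in
# SPR_g(v), the attachment node achieving it, and instrumentation counts.
rsec_core <- function(g, ctx, mid, v, verify = FALSE) {
  if (is.na(g$parent[v])) stop("v must not be the root of the gene tree")
  gb <- build_gbar(g, v)
  par <- gb$parent; k1 <- gb$kid1; k2 <- gb$kid2; root <- gb$root
  ix <- ctx$ix; dp <- ctx$dp
  map <- map_gene(gb, ctx)
  sc <- vertex_scores_all(gb, map, dp, mid)
  total0 <- sum(sc)

  x <- par[v]                       # attachment vertex; its slot is fixed
  r0 <- if (k1[x] == v) k2[x] else k1[x]
  running <- 0L
  best <- 0L
  best_at <- r0
  cand <- 1L
  edges <- 0L
  prev_full <- if (verify) map else NULL

  descend <- function(a) {
    for (k in c(k1[a], k2[a])) {
      if (is.na(k)) next
      z <- if (k1[a] == k) k2[a] else k1[a]
      q <- par[x]
      # saved state for the exact undo
      s_k1a <- k1[a]; s_k2a <- k2[a]; s_k1x <- k1[x]; s_k2x <- k2[x]
      s_mx <- map[x]; s_ma <- map[a]; s_sx <- sc[x]; s_sa <- sc[a]
      # one NNI: slide the attachment from above a to above k
      if (is.na(q)) {
        root <<- a; par[a] <<- NA_integer_
      } else {
        if (k1[q] == x) k1[q] <<- a else k2[q] <<- a
        par[a] <<- q
      }
      k1[a] <<- x; k2[a] <<- z; par[x] <<- a
      k1[x] <<- v; k2[x] <<- k; par[k] <<- x
      map[a] <<- s_mx
      map[x] <<- lca1(ix, map[v], map[k])
      sc[x] <<- vscore1(map[x], map[v], map[k], dp, mid)
      sc[a] <<- vscore1(map[a], map[x], map[z], dp, mid)
      delta <- (sc[x] + sc[a]) - (s_sx + s_sa)
      running <<- running + delta
      cand <<- cand + 1L
      edges <<- edges + 1L
      if (verify) {
        cur <- new_rbtree(par, k1, k2, gb$label, root)
        full <- map_gene(cur, ctx)
        if (!identical(full, map))
          stop("internal error: incremental LCA mapping disagrees with full recompute")
        moved <- which(full != prev_full)
        if (!all(moved %in% c(x, a)))
          stop("internal error: NNI step changed the mapping outside the two active vertices")
        raw <- sum(vertex_scores_all(cur, full, dp, mid))
        if (raw - total0 != running)
          stop("internal error: two-vertex delta disagrees with full-recompute score difference")
        prev_full <<- full
      }
      if (running < best) { best <<- running; best_at <<- k }
      descend(k)
      # undo: restore the pre-move state exactly
      if (is.na(q)) {
        root <<- x; par[x] <<- NA_integer_
      } else {
        if (k1[q] == a) k1[q] <<- x else k2[q] <<- x
        par[x] <<- q
      }
      k1[a] <<- s_k1a; k2[a] <<- s_k2a; par[a] <<- x
      k1[x] <<- s_k1x; k2[x] <<- s_k2x; par[k] <<- a
      map[x] <<- s_mx; map[a] <<- s_ma; sc[x] <<- s_sx; sc[a] <<- s_sa
      running <<- running - delta
      if (verify) prev_full <<- map
    }
  }
  descend(r0)
  if (verify) {
    # the undo stack must have restored the root state bit-for-bit
    back <- new_rbtree(par, k1, k2, gb$label, root)
    if (running != 0L || !identical(map_gene(back, ctx), map) ||
        !identical(write_newick(back), write_newick(gb)))
      stop("internal error: walk did not restore the root state")
  }
  list(best_raw = total0 + best, best_at = best_at,
       candidates = cand, edges = edges)
}

finish_correction <- function(g, ctx, mid, model, neighborhood, orig,
                              best_cost, v, at, reroot_at, cand, edges) {
  if (best_cost >= orig) {
    return(new_correction(g, orig, orig, NULL, cand, model, neighborhood, edges))
  }
  g2 <- if (!is.na(reroot_at)) rr_subtree(g, v, reroot_at) else g
  best_tree <- spr(g2, v, at)
  edit <- if (neighborhood == "tbr")
    new_edit("TBR", v, at, reroot_at = if (is.na(reroot_at)) v else reroot_at)
  else new_edit("SPR", v, at)
  new_correction(best_tree, best_cost, orig, edit, cand, model, neighborhood, edges)
}

#' Best regraft position for one pruned subtree (restricted SPR search)
#'
#' Finds the minimum-cost tree among all SPR rearrangements that prune the
#' subtree at `v`, in time linear in the tree size, by the incremental
#' NNI-adjacency walk. If no rearrangement strictly improves on the input
#' tree, the input is returned with `edit = NULL`.
#'
#' @param g Gene `rbtree`.
#' @param s Species `rbtree`.
#' @param v Non-root node id of `g` (the pruned subtree).
#' @param model One of `"dup"`, `"duploss"`, `"deepcoal"`.
#' @param species_delimiter Optional label-resolution delimiter.
#' @param verify If `TRUE`, every incremental step is checked against a
#'   full recomputation (slow; a bug trap, not a user mode).
#' @return A `gt_correction` with fields `best_tree`, `best_cost`,
#'   `original_cost`, `edit`, `candidates_examined`.
#' @export
solve_r_sec <- function(g, s, v, model, species_delimiter = NULL, verify = FALSE) {
  mid <- model_id(model)
  ctx <- species_context(g, s, species_delimiter)
  orig <- recon_cost_ctx(g, ctx, mid)
  norm <- if (mid == 3L) ctx$n_edges else 0L
  r <- rsec_core(g, ctx, mid, v, verify)
  finish_correction(g, ctx, mid, match.arg(model, COST_MODELS), "spr", orig,
                    r$best_raw - norm, v, r$best_at, NA_integer_,
                    r$candidates, if (verify) r$edges else NA_integer_)
}

#' Error-correct a gene tree within its SPR or TBR neighborhood
#'
#' `solve_sec()` searches the full SPR neighborhood of `g` (every pruned
#' subtree, every regraft position) for the topology of minimum
#' reconciliation cost against `s`; `solve_tec()` searches the larger TBR
#' neighborhood, additionally rerooting each pruned subtree optimally.
#' Both run in quadratic time in the number of leaves. Ties are broken
#' toward the first candidate in a fixed preorder traversal; if the input
#' tree's cost ties the neighborhood minimum, the input is returned
#' unchanged with `edit = NULL`.
#'
#' @inheritParams solve_r_sec
#' @return A `gt_correction`.
#' @examples
#' g <- parse_newick("((A,C),B);"); s <- parse_newick("((A,B),C);")
#' res <- solve_sec(g, s, "deepcoal")
#' res$best_cost
#' write_newick(res$best_tree)
#' @export
solve_sec <- function(g, s, model, species_delimiter = NULL, verify = FALSE) {
  mid <- model_id(model)
  ctx <- species_context(g, s, species_delimiter)
  orig <- recon_cost_ctx(g, ctx, mid)
  model <- match.arg(model, COST_MODELS)
  if (n_leaves(g) < 3L)
    return(new_correction(g, orig, orig, NULL, 0L, model, "spr"))
  norm <- if (mid == 3L) ctx$n_edges else 0L
  best <- NULL
  cand <- 0L; edges <- 0L
  for (v in preorder_nodes(g)[-1L]) {
    r <- rsec_core(g, ctx, mid, v, verify)
    cand <- cand + r$candidates
    edges <- edges + r$edges
    if (is.null(best) || r$best_raw < best$best_raw) {
      best <- r; best$v <- v
    }
  }
  finish_correction(g, ctx, mid, model, "spr", orig, best$best_raw - norm,
                    best$v, best$best_at, NA_integer_, cand,
                    if (verify) edges else NA_integer_)
}

# Constant-time-per-edge rooting scan over the subtree rooted at rho
# (operating on full-tree vectors; only subtree slots are touched).
# Returns the best rerooting node (rho for the identity), the raw score
# delta it achieves, and the number of rootings examined.
root_scan_core <- function(t, rho, ctx, mid, map, sc) {
  par <- t$parent; k1 <- t$kid1; k2 <- t$kid2
  ix <- ctx$ix; dp <- ctx$dp
  running <- 0L; best <- 0L; best_x <- rho; cand <- 1L
  descend <- function(b) {
    for (cc in c(k1[b], k2[b])) {
      if (is.na(cc)) next
      d <- if (k1[rho] == b) k2[rho] else k1[rho]
      c2 <- if (k1[b] == cc) k2[b] else k1[b]
      s_k1r <- k1[rho]; s_k2r <- k2[rho]; s_k1b <- k1[b]; s_k2b <- k2[b]
      s_mb <- map[b]; s_sr <- sc[rho]; s_sb <- sc[b]
      # slide the root across edge (b, cc): rho -> {cc, b}, b -> {c2, d}
      k1[rho] <<- cc; k2[rho] <<- b; par[cc] <<- rho
      k1[b] <<- c2; k2[b] <<- d; par[d] <<- b
      map[b] <<- lca1(ix, map[c2], map[d])
      sc[b] <<- vscore1(map[b], map[c2], map[d], dp, mid)
      sc[rho] <<- vscore1(map[rho], map[cc], map[b], dp, mid)
      delta <- (sc[rho] + sc[b]) - (s_sr + s_sb)
      running <<- running + delta
      cand <<- cand + 1L
      if (running < best) { best <<- running; best_x <<- cc }
      descend(cc)
      # undo
      k1[rho] <<- s_k1r; k2[rho] <<- s_k2r; par[cc] <<- b
      k1[b] <<- s_k1b; k2[b] <<- s_k2b; par[d] <<- rho
      map[b] <<- s_mb; sc[rho] <<- s_sr; sc[b] <<- s_sb
      running <<- running - delta
    }
  }
  if (!is.na(k1[rho])) { descend(k1[rho]); descend(k2[rho]) }
  list(best_x = best_x, best_delta = best, candidates = cand)
}

#' Best rooting of a (pruned) gene subtree
#'
#' Finds the rerooting `RR(gv, x)` minimizing the sum of per-vertex
#' reconciliation scores over the subtree's internal vertices (no
#' deep-coalescence normalization: the quantity that enters the TBR
#' decomposition). The root vertex's mapping is the LCA of all leaf images
#' and is identical under every rerooting. The fast method slides the root
#' across one edge at a time with the same two-vertex constant-time updates
#' as the SPR walk; `method = "exhaustive"` scores every rerooting from
#' scratch via [reroot()], as a cross-check.
#'
#' @param gv An `rbtree` (a pruned gene subtree).
#' @param s Species `rbtree`.
#' @param model One of `"dup"`, `"duploss"`, `"deepcoal"`.
#' @param species_delimiter Optional label-resolution delimiter.
#' @param method `"fast"` (default) or `"exhaustive"`.
#' @return A list with `root_at` (node id in `gv`), `cost` (the minimal raw
#'   score sum), and `candidates` (rootings examined).
#' @export
best_rooting <- function(gv, s, model, species_delimiter = NULL,
                         method = c("fast", "exhaustive")) {
  method <- match.arg(method)
  mid <- model_id(model)
  ctx <- species_context(gv, s, species_delimiter)
  if (n_leaves(gv) == 1L)
    return(list(root_at = gv$root, cost = 0L, candidates = 1L))
  map <- map_gene(gv, ctx)
  sc <- vertex_scores_all(gv, map, ctx$dp, mid)
  total0 <- sum(sc)
  if (method == "fast") {
    r <- root_scan_core(gv, gv$root, ctx, mid, map, sc)
    return(list(root_at = r$best_x, cost = total0 + r$best_delta,
                candidates = r$candidates))
  }
  best <- total0; best_x <- gv$root; cand <- 0L
  for (x in preorder_nodes(gv)) {
    rt <- reroot(gv, x)
    m2 <- map_gene(rt, ctx)
    raw <- sum(vertex_scores_all(rt, m2, ctx$dp, mid))
    cand <- cand + 1L
    if (raw < best) { best <- raw; best_x <- x }
  }
  list(root_at = best_x, cost = best, candidates = cand)
}

# One restricted TBR problem given a prebuilt context.
rtec_core <- function(g, ctx, mid, v, verify = FALSE) {
  reroot_at <- NA_integer_
  g2 <- g
  cand0 <- 0L
  if (!is.na(g$kid1[v])) {
    map <- map_gene(g, ctx)
    sc <- vertex_scores_all(g, map, ctx$dp, mid)
    rs <- root_scan_core(g, v, ctx, mid, map, sc)
    cand0 <- rs$candidates
    if (rs$best_x != v) {
      reroot_at <- rs$best_x
      g2 <- rr_subtree(g, v, rs$best_x)
    }
  }
  r <- rsec_core(g2, ctx, mid, v, verify)
  list(best_raw = r$best_raw, best_at = r$best_at, reroot_at = reroot_at,
       candidates = cand0 + r$candidates, edges = r$edges)
}

#' @rdname solve_r_sec
#' @export
solve_r_tec <- function(g, s, v, model, species_delimiter = NULL, verify = FALSE) {
  mid <- model_id(model)
  ctx <- species_context(g, s, species_delimiter)
  if (is.na(g$parent[v])) stop("v must not be the root of the gene tree")
  orig <- recon_cost_ctx(g, ctx, mid)
  norm <- if (mid == 3L) ctx$n_edges else 0L
  r <- rtec_core(g, ctx, mid, v, verify)
  finish_correction(g, ctx, mid, match.arg(model, COST_MODELS), "tbr", orig,
                    r$best_raw - norm, v, r$best_at, r$reroot_at,
                    r$candidates, if (verify) r$edges else NA_integer_)
}

#' @rdname solve_sec
#' @export
solve_tec <- function(g, s, model, species_delimiter = NULL, verify = FALSE) {
  mid <- model_id(model)
  ctx <- species_context(g, s, species_delimiter)
  orig <- recon_cost_ctx(g, ctx, mid)
  model <- match.arg(model, COST_MODELS)
  if (n_leaves(g) < 3L)
    return(new_correction(g, orig, orig, NULL, 0L, model, "tbr"))
  norm <- if (mid == 3L) ctx$n_edges else 0L
  best <- NULL
  cand <- 0L; edges <- 0L
  for (v in preorder_nodes(g)[-1L]) {
    r <- rtec_core(g, ctx, mid, v, verify)
    cand <- cand + r$candidates
    edges <- edges + r$edges
    if (is.null(best) || r$best_raw < best$best_raw) {
      best <- r; best$v <- v
    }
  }
  finish_correction(g, ctx, mid, model, "tbr", orig, best$best_raw - norm,
                    best$v, best$best_at, best$reroot_at, cand,
                    if (verify) edges else NA_integer_)
}
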