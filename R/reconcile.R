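# LCA mapping of a gene tree into a species tree and the duplication,
# duplication-loss, and deep-coalescence reconciliation costs.
#
# Conventions used throughout:
#  * Gene leaf labels resolve to species labels either verbatim or, when a
#    delimiter is given, by taking the prefix before its first occurrence
#    ("speciesX_gene1" -> "speciesX").
#  * Before any cost is computed the species tree is restricted to the
#    species actually sampled in the gene tree (S_effective), so the leaf
#    mapping is a surjection and the deep-coalescence normalization never
#    goes negative on under-sampled families.
#  * All costs are exact integers.

COST_MODELS <- c("dup", "duploss", "deepcoal")

model_id <- function(model) {
  model <- match.arg(model, COST_MODELS)
  match(model, COST_MODELS)
}

resolve_labels <- function(labels, species_delimiter = NULL) {
  if (is.null(species_delimiter)) return(labels)
  if (!is.character(species_delimiter) || nchar(species_delimiter) != 1L)
    stop("`species_delimiter` must be a single character")
  vapply(strsplit(labels, species_delimiter, fixed = TRUE),
         function(x) x[[1L]], character(1))
}

#' Restrict a species tree to a subset of its species
#'
#' Returns the rooted tree spanning exactly the named leaves, with every
#' suppressible degree-two vertex removed; the result is again full binary.
#'
#' @param s A species `rbtree` (unique leaf labels).
#' @param labels Character vector of species labels to keep (non-empty).
#' @return An `rbtree` with fresh, compact node ids.
#' @examples
#' write_newick(restrict_species_tree(parse_newick("((A,B),C);"), c("A", "C")))
#' @export
restrict_species_tree <- function(s, labels) {
  labels <- unique(labels)
  if (length(labels) == 0L) stop("`labels` must be non-empty")
  slabs <- s$label
  unknown <- setdiff(labels, slabs[!is.na(slabs)])
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  keep <- !is.na(slabs) & slabs %in% labels

  n <- n_nodes(s)
  m <- 2L * length(labels) - 1L
  par <- rep(NA_integer_, m); c1 <- rep(NA_integer_, m); c2 <- rep(NA_integer_, m)
  lab <- rep(NA_character_, m)
  newid <- integer(n)                  # 0 = dropped
  nn <- 0L
  for (v in postorder_nodes(s)) {
    if (is.na(s$kid1[v])) {
      if (keep[v]) {
        nn <- nn + 1L; newid[v] <- nn; lab[nn] <- slabs[v]
      }
    } else {
      a <- newid[s$kid1[v]]; b <- newid[s$kid2[v]]
      if (a > 0L && b > 0L) {
        nn <- nn + 1L; newid[v] <- nn
        c1[nn] <- a; c2[nn] <- b; par[a] <- nn; par[b] <- nn
      } else if (a > 0L) newid[v] <- a
      else if (b > 0L) newid[v] <- b
    }
  }
  new_rbtree(par[seq_len(nn)], c1[seq_len(nn)], c2[seq_len(nn)],
             lab[seq_len(nn)], newid[s$root])
}

# Shared per-(gene, species) context: effective species tree, its LCA
# index, and the leaf lookup table. Built once and threaded through the
# solvers and the oracle.
species_context <- function(g, s, species_delimiter = NULL) {
  glabs <- resolve_labels(tree_labels(g), species_delimiter)
  slabs <- tree_labels(s)
  bad <- setdiff(unique(glabs), slabs)
  if (length(bad))
    stop("incomparable trees: gene leaf label(s) not in species tree: ",
         paste(bad, collapse = ", "))
  s_eff <- restrict_species_tree(s, unique(glabs))
  ix <- build_lca_index(s_eff)
  leaf_ids <- tree_leaves(s_eff)
  leaf_of <- stats::setNames(leaf_ids, s_eff$label[leaf_ids])
  list(s_eff = s_eff, ix = ix, dp = ix$depth, leaf_of = leaf_of,
       delim = species_delimiter,
       n_edges = if (n_nodes(s_eff) > 1L) n_nodes(s_eff) - 1L else 0L)
}

# LCA mapping as a bare integer vector over the nodes of g (gene node id ->
# species node id in ctx$s_eff), computed bottom-up.
map_gene <- function(g, ctx) {
  n <- n_nodes(g)
  map <- integer(n)
  lv <- tree_leaves(g)
  map[lv] <- ctx$leaf_of[resolve_labels(g$label[lv], ctx$delim)]
  if (anyNA(map[lv]))
    stop("incomparable trees: unmappable gene leaf label")
  ix <- ctx$ix
  for (v in postorder_nodes(g)) {
    if (!is.na(g$kid1[v])) map[v] <- lca1(ix, map[g$kid1[v]], map[g$kid2[v]])
  }
  map
}

# Vectorized per-internal-vertex scores; returns a full-length vector with
# zeros at leaves so it can be indexed by node id.
vertex_scores_all <- function(g, map, dp, mid) {
  sc <- integer(n_nodes(g))
  int <- which(!is.na(g$kid1))
  if (!length(int)) return(sc)
  mg <- map[int]; m1 <- map[g$kid1[int]]; m2 <- map[g$kid2[int]]
  if (mid == 1L) {
    sc[int] <- as.integer(m1 == mg | m2 == mg)
  } else if (mid == 2L) {
    dupv <- as.integer(m1 == mg | m2 == mg)
    loss <- ifelse(m1 == mg & m2 == mg, 0L,
                   abs(dp[m1] - dp[mg] - 1L) + abs(dp[m2] - dp[mg] - 1L))
    sc[int] <- dupv + as.integer(loss)
  } else {
    sc[int] <- dp[m1] + dp[m2] - 2L * dp[mg]
  }
  sc
}

# scalar version used by the incremental solvers
vscore1 <- function(mg, m1, m2, dp, mid) {
  if (mid == 1L) {
    if (m1 == mg || m2 == mg) 1L else 0L
  } else if (mid == 2L) {
    d <- if (m1 == mg || m2 == mg) 1L else 0L
    loss <- if (m1 == mg && m2 == mg) 0L
            else abs(dp[m1] - dp[mg] - 1L) + abs(dp[m2] - dp[mg] - 1L)
    d + loss
  } else {
    dp[m1] + dp[m2] - 2L * dp[mg]
  }
}

recon_cost_ctx <- function(g, ctx, mid, map = NULL) {
  if (is.null(map)) map <- map_gene(g, ctx)
  raw <- sum(vertex_scores_all(g, map, ctx$dp, mid))
  if (mid == 3L) raw - ctx$n_edges else raw
}

#' LCA mapping of a gene tree into a species tree
#'
#' Maps every gene-tree vertex to the most recent species-tree vertex that
#' could contain it: leaves map to the species leaf carrying the same
#' (resolved) label, internal vertices to the least common ancestor of
#' their children's images. The species tree is first restricted to the
#' species present in the gene tree.
#'
#' @param g Gene `rbtree` (labels may repeat for multi-copy families).
#' @param s Species `rbtree` (unique labels).
#' @param species_delimiter Optional single character; gene labels resolve
#'   to the prefix before its first occurrence.
#' @return An object of class `lca_mapping` with fields `gene`, `species`
#'   (the restricted species tree), `map` (integer vector, gene node id to
#'   species node id) and `species_index` (an `lca_index`).
#' @examples
#' m <- lca_mapping(parse_newick("((A,C),B);"), parse_newick("((A,B),C);"))
#' m$map
#' @export
lca_mapping <- function(g, s, species_delimiter = NULL) {
  ctx <- species_context(g, s, species_delimiter)
  structure(list(gene = g, species = ctx$s_eff, map = map_gene(g, ctx),
                 species_index = ctx$ix, ctx = ctx),
            class = "lca_mapping")
}

#' @export
print.lca_mapping <- function(x, ...) {
  cat(sprintf("LCA mapping: %d gene nodes -> species tree with %d leaves\n",
              n_nodes(x$gene), n_leaves(x$species)))
  invisible(x)
}

#' Per-vertex reconciliation score
#'
#' The cost contribution of one internal gene-tree vertex `g` under the
#' chosen model: for `"dup"`, 1 if the vertex maps to the same species
#' vertex as one of its children; for `"duploss"`, the loss count (0 when
#' both children map with the vertex, otherwise the summed depth gaps minus
#' one per child) plus 1 for a duplication; for `"deepcoal"`, the number of
#' species-tree edges between the vertex's image and each child's image.
#'
#' @param m An `lca_mapping`.
#' @param g Internal gene node id.
#' @param model One of `"dup"`, `"duploss"`, `"deepcoal"`.
#' @return Non-negative integer.
#' @export
vertex_score <- function(m, g, model) {
  stopifnot(inherits(m, "lca_mapping"))
  mid <- model_id(model)
  gt <- m$gene
  if (is.na(gt$kid1[g])) stop("vertex_score() is defined for internal gene nodes only")
  vscore1(m$map[g], m$map[gt$kid1[g]], m$map[gt$kid2[g]],
          m$species_index$depth, mid)
}

#' Reconciliation cost between a gene tree and a species tree
#'
#' Sum of the per-vertex scores over internal gene-tree vertices; for the
#' deep-coalescence model the edge count of the (restricted) species tree
#' is subtracted, so congruent one-copy trees cost 0 under every model.
#'
#' @inheritParams lca_mapping
#' @param model One of `"dup"`, `"duploss"`, `"deepcoal"`.
#' @return Integer cost (non-negative).
#' @examples
#' g <- parse_newick("((A,C),B);"); s <- parse_newick("((A,B),C);")
#' reconciliation_cost(g, s, "dup")       # 1
#' reconciliation_cost(g, s, "duploss")   # 4
#' reconciliation_cost(g, s, "deepcoal")  # 1
#' @export
reconciliation_cost <- function(g, s, model, species_delimiter = NULL) {
  mid <- model_id(model)
  ctx <- species_context(g, s, species_delimiter)
  recon_cost_ctx(g, ctx, mid)
}
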