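# Seeded generation of species trees and corrupted gene trees. The
# generator emulates the shape of a curated gene-family cohort (a fixed
# species tree; one gene tree per family, congruent up to a small number of
# topological errors, optional same-species duplicates and unsampled
# species) so every solver can be exercised without external data.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the gene-tree corruption generator
#'
#' @param n_taxa Number of species (>= 2).
#' @param dup_leaf_prob Probability that a sampled species leaf is expanded
#'   into a same-label cherry (a gene duplication), in `[0, 1]`.
#' @param n_spr_errors Number of uniformly random topology-changing SPR
#'   moves applied to the gene tree (>= 0).
#' @param drop_leaf_prob Probability that a species is unsampled in the
#'   gene tree (at least two species are always kept), in `[0, 1]`.
#' @param seed Integer RNG seed; generation is a pure function of the
#'   configuration.
#' @return A `gen_config` list.
#' @export
gen_config <- function(n_taxa, dup_leaf_prob = 0, n_spr_errors = 0,
                       drop_leaf_prob = 0, seed = 1L) {
  stopifnot(n_taxa >= 2, dup_leaf_prob >= 0, dup_leaf_prob <= 1,
            drop_leaf_prob >= 0, drop_leaf_prob <= 1, n_spr_errors >= 0)
  structure(list(n_taxa = as.integer(n_taxa),
                 dup_leaf_prob = dup_leaf_prob,
                 n_spr_errors = as.integer(n_spr_errors),
                 drop_leaf_prob = drop_leaf_prob,
                 seed = as.integer(seed)),
            class = "gen_config")
}

#' Random species tree under a Yule (random-split) growth process
#'
#' Starts from a two-species cherry and repeatedly splits a uniformly
#' chosen leaf until `n_taxa` leaves exist; leaves are labeled `sp01`,
#' `sp02`, ... in preorder. Identical `(n_taxa, seed)` give identical
#' trees.
#'
#' @param n_taxa Number of species (>= 2).
#' @param seed Integer RNG seed.
#' @return An `rbtree`.
#' @examples
#' write_newick(random_species_tree(5, seed = 1))
#' @export
random_species_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  n_taxa <- as.integer(n_taxa)
  with_seed(seed, {
    m <- 2L * n_taxa - 1L
    par <- rep(NA_integer_, m); c1 <- rep(NA_integer_, m); c2 <- rep(NA_integer_, m)
    c1[1L] <- 2L; c2[1L] <- 3L; par[2L] <- 1L; par[3L] <- 1L
    nn <- 3L
    leaves <- c(2L, 3L)
    while (length(leaves) < n_taxa) {
      i <- if (length(leaves) == 1L) 1L else sample.int(length(leaves), 1L)
      v <- leaves[i]
      a <- nn + 1L; b <- nn + 2L; nn <- nn + 2L
      c1[v] <- a; c2[v] <- b; par[a] <- v; par[b] <- v
      leaves <- c(leaves[-i], a, b)
    }
    lab <- rep(NA_character_, m)
    t <- new_rbtree(par, c1, c2, lab, 1L)
    width <- max(2L, nchar(as.character(n_taxa)))
    lv <- preorder_nodes(t)
    lv <- lv[is.na(t$kid1[lv])]
    t$label[lv] <- sprintf(paste0("sp%0", width, "d"), seq_along(lv))
    t
  })
}

# expand leaf v of t into a same-label cherry (two new leaf slots appended)
expand_leaf <- function(t, v) {
  lab <- t$label[v]
  n <- n_nodes(t)
  a <- n + 1L; b <- n + 2L
  t$parent <- c(t$parent, v, v)
  t$kid1 <- c(t$kid1, NA_integer_, NA_integer_)
  t$kid2 <- c(t$kid2, NA_integer_, NA_integer_)
  t$label <- c(t$label, lab, lab)
  t$kid1[v] <- a; t$kid2[v] <- b
  t$label[v] <- NA_character_
  t
}

#' Generate a corrupted gene tree from a species tree
#'
#' Starts from a one-copy gene tree congruent to `s`; drops each species
#' leaf with probability `drop_leaf_prob` (always keeping at least two, or
#' at least three when SPR errors are requested, since a topology-changing
#' SPR needs three leaves);
#' expands each surviving leaf into a same-label cherry with probability
#' `dup_leaf_prob`; then applies `n_spr_errors` uniformly random
#' topology-changing SPR moves (draws that reproduce the current topology
#' are rejected and redrawn). With no SPR errors the duplication cost of
#' the result equals the number of cherry expansions and its
#' deep-coalescence cost is 0.
#'
#' @param s Species `rbtree`.
#' @param cfg A [gen_config()]; its `n_taxa` is ignored in favor of `s`.
#' @return A list with `tree` (the corrupted gene `rbtree`), `edits` (list
#'   of the applied SPR `edit_descriptor`s), `n_dup` (cherry expansions)
#'   and `dropped` (labels of unsampled species).
#' @export
corrupt_gene_tree <- function(s, cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  with_seed(cfg$seed, {
    labs <- tree_labels(s)
    keep <- stats::runif(length(labs)) >= cfg$drop_leaf_prob
    # a topology-changing SPR needs >= 3 leaves
    min_keep <- if (cfg$n_spr_errors > 0L) 3L else 2L
    min_keep <- min(min_keep, length(labs))
    while (sum(keep) < min_keep) keep[sample.int(length(keep), 1L)] <- TRUE
    g <- restrict_species_tree(s, labs[keep])
    n_dup <- 0L
    for (v in tree_leaves(g)) {
      if (stats::runif(1L) < cfg$dup_leaf_prob) {
        g <- expand_leaf(g, v)
        n_dup <- n_dup + 1L
      }
    }
    edits <- list()
    if (cfg$n_spr_errors > 0L) {
      if (n_leaves(g) < 3L)
        stop("cannot apply a topology-changing SPR to a tree with < 3 leaves")
      for (i in seq_len(cfg$n_spr_errors)) {
        cur <- canonical_form(g)
        for (tries in seq_len(500L)) {
          nodes <- preorder_nodes(g)[-1L]
          v <- nodes[sample.int(length(nodes), 1L)]
          ys <- spr_targets(g, v)
          y <- ys[sample.int(length(ys), 1L)]
          g2 <- spr(g, v, y)
          if (canonical_form(g2) != cur) {
            g <- g2
            edits[[length(edits) + 1L]] <- new_edit("SPR", v, y)
            break
          }
          if (tries == 500L)
            stop("could not draw a topology-changing SPR move")
        }
      }
    }
    list(tree = g, edits = edits, n_dup = n_dup, dropped = labs[!keep])
  })
}

#' Generate a synthetic gene-family cohort
#'
#' A species tree plus `n_genes` corrupted gene trees (seeds
#' `gene_seed_base + 0 .. n_genes - 1`), mirroring the shape of a
#' single-copy gene-family study: by default 8 taxa and 106 families, each
#' perturbed by exactly one random SPR. Optionally writes `species.nwk`,
#' `genes.nwk` (one Newick per line) and `edits.tsv` (the ground-truth
#' corruption log) to `dir`.
#'
#' @param n_taxa Species count (default 8).
#' @param n_genes Number of gene trees (default 106).
#' @param n_spr_errors SPR corruptions per gene (default 1).
#' @param dup_leaf_prob,drop_leaf_prob Per-leaf corruption probabilities
#'   (default 0).
#' @param species_seed Seed for the species tree (default 1).
#' @param gene_seed_base First gene seed (default 0).
#' @param dir Optional output directory.
#' @return A list with `species` (`rbtree`), `genes` (list of `rbtree`),
#'   `edits` (data frame: gene, move, pruned, regraft), and the paths
#'   written (if any).
#' @export
make_cohort <- function(n_taxa = 8L, n_genes = 106L, n_spr_errors = 1L,
                        dup_leaf_prob = 0, drop_leaf_prob = 0,
                        species_seed = 1L, gene_seed_base = 0L, dir = NULL) {
  s <- random_species_tree(n_taxa, seed = species_seed)
  genes <- vector("list", n_genes)
  rows <- list()
  for (i in seq_len(n_genes)) {
    cfg <- gen_config(n_taxa, dup_leaf_prob = dup_leaf_prob,
                      n_spr_errors = n_spr_errors,
                      drop_leaf_prob = drop_leaf_prob,
                      seed = gene_seed_base + i - 1L)
    cg <- corrupt_gene_tree(s, cfg)
    genes[[i]] <- cg$tree
    for (e in cg$edits)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = i, move = e$kind, pruned = e$pruned,
        regraft = e$regraft_above)
  }
  edits <- if (length(rows)) do.call(rbind, rows)
           else data.frame(gene = integer(0), move = character(0),
                           pruned = integer(0), regraft = integer(0))
  out <- list(species = s, genes = genes, edits = edits)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sp <- file.path(dir, "species.nwk")
    gp <- file.path(dir, "genes.nwk")
    ep <- file.path(dir, "edits.tsv")
    writeLines(write_newick(s), sp)
    write_newick_lines(genes, gp)
    utils::write.table(edits, ep, sep = "\t", row.names = FALSE, quote = FALSE)
    out$paths <- c(species = sp, genes = gp, edits = ep)
  }
  out
}
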