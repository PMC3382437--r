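# Shared fixtures and independent brute-force oracles for the test suite.
# Everything here is deliberately naive: ancestor walks, explicit leaf-set
# LCAs, full topology enumeration.

expect_valid_tree <- function(t) {
  expect_true(gtcorrect:::validate_tree(t))
}

naive_ancestors <- function(t, v) {
  out <- v
  while (!is.na(t$parent[v])) {
    v <- t$parent[v]
    out <- c(out, v)
  }
  out
}

naive_lca <- function(t, u, v) {
  au <- naive_ancestors(t, u)
  av <- naive_ancestors(t, v)
  au[au %in% av][1L]
}

naive_depth <- function(t, v) length(naive_ancestors(t, v)) - 1L

# LCA mapping computed from leaf-label sets only (no index, no recursion
# on children): the image of a gene vertex is the iterated pairwise naive
# LCA of the species leaves carrying its subtree's labels.
naive_mapping <- function(g, s_eff) {
  slv <- tree_leaves(s_eff)
  leaf_of <- stats::setNames(slv, s_eff$label[slv])
  vapply(seq_len(n_nodes(g)), function(v) {
    labs <- g$label[intersect(subtree_nodes(g, v), tree_leaves(g))]
    ids <- unname(leaf_of[unique(labs)])
    Reduce(function(a, b) naive_lca(s_eff, a, b), ids)
  }, integer(1))
}

# attach a new leaf on the edge above v (above the root when v is the root)
attach_leaf_above <- function(t, v, lab) {
  n <- n_nodes(t)
  ni <- n + 1L; nl <- n + 2L
  t$parent <- c(t$parent, NA_integer_, NA_integer_)
  t$kid1 <- c(t$kid1, NA_integer_, NA_integer_)
  t$kid2 <- c(t$kid2, NA_integer_, NA_integer_)
  t$label <- c(t$label, NA_character_, lab)
  p <- t$parent[v]
  if (is.na(p)) t$root <- ni
  else {
    t <- gtcorrect:::replace_child(t, p, v, ni)
    t$parent[ni] <- p
  }
  t$kid1[ni] <- v; t$kid2[ni] <- nl
  t$parent[v] <- ni; t$parent[nl] <- ni
  t
}

# every rooted binary topology over a label vector (15 for 4 labels)
all_rooted_trees <- function(labels) {
  trees <- list(parse_newick(paste0(labels[1L], ";")))
  for (lab in labels[-1L]) {
    nxt <- vector("list", 0L)
    for (t in trees) {
      for (v in seq_len(n_nodes(t))) {
        nxt[[length(nxt) + 1L]] <- attach_leaf_above(t, v, lab)
      }
    }
    trees <- nxt
  }
  trees
}

canon_set <- function(trees) {
  unique(vapply(trees, canonical_form, character(1)))
}

# a corrupted random instance for randomized cross-checks
rand_instance <- function(n, seed, dup = 0.15, drop = 0.1, nerr = 1) {
  s <- random_species_tree(n, seed = seed)
  cg <- corrupt_gene_tree(s, gen_config(n, dup_leaf_prob = dup,
                                        n_spr_errors = nerr,
                                        drop_leaf_prob = drop,
                                        seed = seed + 77L))
  list(s = s, g = cg$tree, gen = cg)
}

MODELS <- c("dup", "duploss", "deepcoal")
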