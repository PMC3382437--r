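test_that("species-tree restriction keeps exactly the named leaves", {
  s <- parse_newick("((A,B),C);")
  expect_true(is_isomorphic(restrict_species_tree(s, c("A", "B")),
                            parse_newick("(A,B);")))
  expect_true(is_isomorphic(restrict_species_tree(s, c("A", "C")),
                            parse_newick("(A,C);")))
  expect_true(is_isomorphic(restrict_species_tree(s, c("A", "B", "C")), s))
  expect_error(restrict_species_tree(s, c("A", "Z")), "species not in tree.*Z")

  big <- random_species_tree(20, seed = 9)
  keep <- tree_labels(big)[c(1, 4, 7, 11, 18)]
  r <- restrict_species_tree(big, keep)
  expect_valid_tree(r)
  expect_setequal(tree_labels(r), keep)
})

test_that("LCA mapping matches the leaf-set oracle and is monotone", {
  g <- parse_newick("((A,C),B);")
  s <- parse_newick("((A,B),C);")
  m <- lca_mapping(g, s)
  ref <- naive_mapping(g, m$species)
  expect_identical(m$map, ref)
  expect_equal(m$map[g$root], m$species$root)        # root maps to root
  expect_equal(m$map[2L], m$species$root)            # (A,C) forced to root

  # multi-copy family
  g2 <- parse_newick("((A,A),B);")
  m2 <- lca_mapping(g2, s)
  expect_identical(m2$map, naive_mapping(g2, m2$species))
  expect_equal(n_leaves(m2$species), 2L)             # restricted to {A,B}

  # randomized agreement + monotonicity (child image below parent image)
  for (i in 1:25) {
    inst <- rand_instance(4 + (i %% 7), seed = 300 + i)
    mm <- lca_mapping(inst$g, inst$s)
    expect_identical(mm$map, naive_mapping(inst$g, mm$species))
    ix <- mm$species_index
    for (v in seq_len(n_nodes(inst$g))) {
      p <- inst$g$parent[v]
      if (!is.na(p))
        expect_equal(lca(ix, mm$map[v], mm$map[p]), mm$map[p])
    }
  }
  expect_error(lca_mapping(parse_newick("(A,Z);"), s), "incomparable.*Z")
})

test_that("worked 3-taxon costs are exact under all three models", {
  g <- parse_newick("((A,C),B);")
  s <- parse_newick("((A,B),C);")
  expect_identical(reconciliation_cost(g, s, "dup"), 1L)
  expect_identical(reconciliation_cost(g, s, "duploss"), 4L)
  expect_identical(reconciliation_cost(g, s, "deepcoal"), 1L)

  m <- lca_mapping(g, s)
  expect_identical(vertex_score(m, g$root, "dup"), 1L)
  expect_identical(vertex_score(m, g$root, "duploss"), 3L)
  expect_identical(vertex_score(m, g$root, "deepcoal"), 2L)
  expect_identical(vertex_score(m, 2L, "dup"), 0L)        # the (A,C) vertex
  expect_identical(vertex_score(m, 2L, "duploss"), 1L)
  expect_identical(vertex_score(m, 2L, "deepcoal"), 3L)
  expect_error(vertex_score(m, 3L, "dup"), "internal")

  g2 <- parse_newick("((A,A),B);")
  expect_identical(reconciliation_cost(g2, s, "dup"), 1L)
  expect_identical(reconciliation_cost(g2, s, "duploss"), 1L)
  expect_identical(reconciliation_cost(g2, s, "deepcoal"), 0L)
})

test_that("congruent one-copy trees cost zero; zero cost implies congruence", {
  # exhaustive 4-leaf instances, both directions of the iff
  trees <- all_rooted_trees(c("A", "B", "C", "D"))
  expect_length(trees, 15L)
  for (g in trees) for (s in trees) {
    costs <- vapply(MODELS, function(m) reconciliation_cost(g, s, m), integer(1))
    if (is_isomorphic(g, s)) expect_true(all(costs == 0L))
    else expect_true(any(costs > 0L))
    expect_true(all(costs >= 0L))
    expect_gte(costs[["duploss"]], costs[["dup"]])
  }
  # 5-leaf instances against one fixed species tree
  s5 <- parse_newick("(((A,B),(C,D)),E);")
  for (g in all_rooted_trees(c("A", "B", "C", "D", "E"))) {
    z <- all(vapply(MODELS, function(m) reconciliation_cost(g, s5, m),
                    integer(1)) == 0L)
    expect_identical(z, is_isomorphic(g, s5))
  }
})

test_that("deep coalescence equals the extra-lineage count (exhaustive 4-leaf)", {
  trees <- all_rooted_trees(c("A", "B", "C", "D"))
  for (g in trees) for (s in trees) {
    expect_identical(reconciliation_cost(g, s, "deepcoal"),
                     dc_extra_lineages(g, s))
  }
})

test_that("cost decomposes exactly into per-vertex scores", {
  for (i in 1:20) {
    inst <- rand_instance(5 + (i %% 6), seed = 600 + i)
    m <- lca_mapping(inst$g, inst$s)
    internal <- setdiff(seq_len(n_nodes(inst$g)), tree_leaves(inst$g))
    for (mod in MODELS) {
      total <- sum(vapply(internal, function(v) vertex_score(m, v, mod),
                          integer(1)))
      norm <- if (mod == "deepcoal") n_nodes(m$species) - 1L else 0L
      expect_identical(reconciliation_cost(inst$g, inst$s, mod), total - norm)
    }
  }
})

test_that("costs are invariant under child-order permutation", {
  g1 <- parse_newick("((A,C),(B,D));")
  g2 <- parse_newick("((D,B),(C,A));")
  s1 <- parse_newick("(((A,B),C),D);")
  s2 <- parse_newick("(D,(C,(B,A)));")
  for (m in MODELS) {
    ref <- reconciliation_cost(g1, s1, m)
    expect_identical(reconciliation_cost(g2, s1, m), ref)
    expect_identical(reconciliation_cost(g1, s2, m), ref)
    expect_identical(reconciliation_cost(g2, s2, m), ref)
  }
})

test_that("gene labels resolve through a species delimiter", {
  s <- parse_newick("((A,B),C);")
  g <- parse_newick("((A|g1,C|g2),B|g1);")
  expect_identical(reconciliation_cost(g, s, "dup", species_delimiter = "|"), 1L)
  expect_error(reconciliation_cost(g, s, "dup"), "incomparable")
})
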