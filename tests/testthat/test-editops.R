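leaf_multiset <- function(t) sort(tree_labels(t))

test_that("reroot follows the suppress-and-subdivide rule", {
  t <- parse_newick("((A,B),C);")          # ids: 1 root, 2 (A,B), 3 A, 4 B, 5 C
  expect_true(is_isomorphic(reroot(t, 5L), t))   # child of root: identity
  expect_true(is_isomorphic(reroot(t, 2L), t))
  expect_true(is_isomorphic(reroot(t, t$root), t))
  expect_true(is_isomorphic(reroot(t, 3L), parse_newick("(A,(B,C));")))
  expect_error(reroot(t, 99L), "not in tree")

  t10 <- random_species_tree(10, seed = 21)
  for (x in seq_len(n_nodes(t10))) {
    r <- reroot(t10, x)
    expect_valid_tree(r)
    expect_identical(leaf_multiset(r), leaf_multiset(t10))
    # rerooting is idempotent once x sits under the root
    expect_true(is_isomorphic(reroot(r, x), r))
  }
})

test_that("spr matches the hand-worked cases and preserves leaves", {
  t <- parse_newick("((A,C),B);")          # 1 root, 2 (A,C), 3 A, 4 C, 5 B
  expect_true(is_isomorphic(spr(t, 5L, 3L), parse_newick("((A,B),C);")))
  # null move: regraft above the old sibling reproduces the topology
  expect_true(is_isomorphic(spr(t, 3L, 4L), t))
  # regraft of a root child at the planted-root position
  t2 <- parse_newick("((A,B),C);")
  expect_true(is_isomorphic(spr(t2, 5L, 2L), t2))
  expect_error(spr(t, t$root, 5L), "root")
  expect_error(spr(t, 2L, 3L), "inside pruned")
  expect_error(spr(t, 3L, 2L), "suppressed")
})

test_that("spr equals tbr with x = v, node for node", {
  for (i in 1:15) {
    t <- random_species_tree(6 + (i %% 5), seed = 800 + i)
    nodes <- preorder_nodes(t)[-1L]
    set.seed(i)
    v <- sample(nodes, 1L)
    ys <- gtcorrect:::spr_targets(t, v)
    y <- sample(ys, 1L)
    a <- spr(t, v, y)
    b <- tbr(t, v, v, y)
    expect_identical(a, b)
    # and x a child of the subtree root hits the rerooting identity branch
    if (!is.na(t$kid1[v])) expect_identical(tbr(t, v, t$kid1[v], y), a)
  }
})

test_that("tbr reroots the pruned component before regrafting", {
  t <- parse_newick("(((A,B),C),D);")      # 1 root, 2 ((A,B),C), 3 (A,B), 4 A, 5 B, 6 C, 7 D
  out <- tbr(t, 2L, 4L, 7L)
  expect_true(is_isomorphic(out, parse_newick("((A,(B,C)),D);")))
  expect_valid_tree(out)
  expect_error(tbr(t, 2L, 7L, 7L), "inside the pruned")
  expect_error(tbr(t, 2L, 4L, 3L), "inside pruned")
})

test_that("nni is the grandparent special case of spr and is reversible", {
  t <- parse_newick("((A,B),C);")
  expect_true(is_isomorphic(nni(t, 3L), parse_newick("(A,(B,C));")))
  # cherry child under the root swaps across the root
  expect_true(is_isomorphic(nni(t, 4L), parse_newick("(B,(A,C));")))
  # every NNI has an inverse NNI (exhaustive over 5-leaf trees x vertices)
  for (t5 in all_rooted_trees(c("A", "B", "C", "D", "E"))[seq(1, 105, by = 7)]) {
    for (v in preorder_nodes(t5)[-1L]) {
      t2 <- nni(t5, v)
      back <- vapply(preorder_nodes(t2)[-1L],
                     function(w) is_isomorphic(nni(t2, w), t5), logical(1))
      expect_true(any(back))
    }
  }
})

test_that("neighborhood enumeration has the predicted cardinalities", {
  t <- parse_newick("((A,B),(C,D));")
  v <- 3L                                   # leaf A
  nb <- enumerate_spr(t, v)
  # admissible positions: all nodes outside T_v except the suppressed parent
  expect_length(nb, n_nodes(t) - length(subtree_nodes(t, v)) - 1L)
  for (e in nb) {
    expect_valid_tree(e$tree)
    expect_identical(leaf_multiset(e$tree), leaf_multiset(t))
    expect_match(format(e$edit), "^SPR prune=\\d+ regraft=\\d+$")
  }
  for (i in 1:8) {
    tt <- random_species_tree(5 + (i %% 4), seed = 900 + i)
    for (v in preorder_nodes(tt)[-1L]) {
      nspr <- length(enumerate_spr(tt, v))
      expect_identical(nspr, n_nodes(tt) - length(subtree_nodes(tt, v)) - 1L)
      expect_identical(length(enumerate_tbr(tt, v)),
                       nspr * length(subtree_nodes(tt, v)))
    }
  }
})

test_that("neighborhoods nest: NNI within SPR within TBR (up to isomorphism)", {
  for (seed in c(31, 32, 33)) {
    for (n in c(5, 6)) {
      t <- random_species_tree(n, seed = seed)
      nni_set <- canon_set(lapply(preorder_nodes(t)[-1L], function(v) nni(t, v)))
      spr_set <- canon_set(lapply(enumerate_spr(t), `[[`, "tree"))
      tbr_set <- canon_set(lapply(enumerate_tbr(t), `[[`, "tree"))
      expect_true(all(nni_set %in% spr_set))
      expect_true(all(spr_set %in% tbr_set))
      expect_gt(length(spr_set), length(nni_set))
      expect_gt(length(tbr_set), length(spr_set))
    }
  }
})

test_that("every SPR move has an inverse SPR move", {
  set.seed(7)
  for (i in 1:20) {
    t <- random_species_tree(4 + (i %% 6), seed = 950 + i)
    nodes <- preorder_nodes(t)[-1L]
    v <- sample(nodes, 1L)
    ys <- gtcorrect:::spr_targets(t, v)
    y <- sample(ys, 1L)
    t2 <- spr(t, v, y)
    backs <- canon_set(lapply(enumerate_spr(t2, v), `[[`, "tree"))
    expect_true(canonical_form(t) %in% backs)
  }
})

test_that("edit operations do not mutate their input", {
  t <- parse_newick("(((A,B),C),D);")
  snap <- unserialize(serialize(t, NULL))
  invisible(spr(t, 3L, 7L)); invisible(tbr(t, 2L, 4L, 7L))
  invisible(nni(t, 4L)); invisible(reroot(t, 5L))
  invisible(enumerate_spr(t)); invisible(enumerate_tbr(t, 3L))
  expect_identical(t, snap)
})
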