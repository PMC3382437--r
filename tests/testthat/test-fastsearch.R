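test_that("restricted SPR solver finds the exact neighborhood minimum", {
  g <- parse_newick("((A,C),B);")
  s <- parse_newick("((A,B),C);")
  r <- solve_r_sec(g, s, 5L, "dup")            # prune leaf B
  expect_identical(r$best_cost, 0L)
  expect_true(is_isomorphic(r$best_tree, s))
  expect_identical(r$original_cost, 1L)

  # congruent tree: nothing can beat zero; input returned unchanged
  rc <- solve_r_sec(parse_newick("((A,B),C);"), s, 3L, "duploss")
  expect_identical(rc$best_cost, 0L)
  expect_null(rc$edit)

  # randomized oracle equivalence over every v and model
  for (i in 1:12) {
    inst <- rand_instance(4 + (i %% 5), seed = 1100 + i, nerr = i %% 3)
    for (v in preorder_nodes(inst$g)[-1L]) {
      for (m in MODELS) {
        fast <- solve_r_sec(inst$g, inst$s, v, m)
        ref <- naive_best_in_neighborhood(inst$g, inst$s, m, "spr", v = v)
        expect_identical(fast$best_cost, ref$best_cost)
      }
    }
  }
  expect_error(solve_r_sec(g, s, g$root, "dup"), "root")
})

test_that("full SPR solver is deterministic and honors its contracts", {
  inst <- rand_instance(8, seed = 1500, nerr = 2)
  for (m in MODELS) {
    r1 <- solve_sec(inst$g, inst$s, m)
    r2 <- solve_sec(inst$g, inst$s, m)
    expect_identical(write_newick(r1$best_tree), write_newick(r2$best_tree))
    expect_identical(r1$best_cost, r2$best_cost)
    expect_lte(r1$best_cost, r1$original_cost)
    expect_gt(r1$candidates_examined, 0L)
    # reported cost is the cost of the reported tree
    expect_identical(reconciliation_cost(r1$best_tree, inst$s, m), r1$best_cost)
    # edit descriptor reproduces the reported tree
    if (!is.null(r1$edit)) {
      redo <- spr(inst$g, r1$edit$pruned, r1$edit$regraft_above)
      expect_true(is_isomorphic(redo, r1$best_tree))
    }
  }
  # a tiny gene tree is returned untouched
  tiny <- solve_sec(parse_newick("(sp01,sp02);"), inst$s, "dup")
  expect_null(tiny$edit)
  expect_identical(tiny$candidates_examined, 0L)
})

test_that("debug mode validates every incremental step and the undo stack", {
  # verify = TRUE recomputes mapping and score from scratch at every NNI
  # edge and asserts the two-vertex delta and the restored root state
  inst <- rand_instance(10, seed = 1600, dup = 0.2, nerr = 2)
  for (m in MODELS) {
    r <- solve_sec(inst$g, inst$s, m, verify = TRUE)
    expect_gt(r$edges_checked, 0L)
    expect_identical(r$best_cost,
                     naive_best_in_neighborhood(inst$g, inst$s, m, "spr")$best_cost)
  }
})

test_that("best_rooting: fast scan equals the exhaustive rerooting scan", {
  gv <- parse_newick("((A,B),C);")
  s <- parse_newick("((A,B),C);")
  b <- best_rooting(gv, s, "dup")
  expect_identical(b$cost, 0L)
  expect_true(b$root_at %in% c(gv$root, gv$kid1[gv$root], gv$kid2[gv$root]))
  expect_identical(best_rooting(parse_newick("A;"), s, "dup")$cost, 0L)

  for (i in 1:15) {
    inst <- rand_instance(10, seed = 1700 + i, dup = 0.25, drop = 0.2)
    for (m in MODELS) {
      f <- best_rooting(inst$g, inst$s, m, method = "fast")
      e <- best_rooting(inst$g, inst$s, m, method = "exhaustive")
      expect_identical(f$cost, e$cost)
    }
  }
})

test_that("the pruned subtree's root image is rooting-invariant", {
  # the independence that justifies optimizing rooting and regraft separately
  for (i in 1:10) {
    inst <- rand_instance(8, seed = 1800 + i, dup = 0.2)
    m <- lca_mapping(inst$g, inst$s)
    images <- vapply(preorder_nodes(inst$g), function(x) {
      rt <- reroot(inst$g, x)
      mm <- lca_mapping(rt, inst$s)
      mm$map[rt$root]
    }, integer(1))
    expect_identical(unique(images), m$map[inst$g$root])
  }
})

test_that("restricted TBR solver matches naive TBR enumeration", {
  for (i in 1:10) {
    inst <- rand_instance(4 + (i %% 4), seed = 1900 + i, dup = 0.2, nerr = i %% 2)
    for (v in preorder_nodes(inst$g)[-1L]) {
      m <- MODELS[1 + (i + v) %% 3]
      fast <- solve_r_tec(inst$g, inst$s, v, m)
      ref <- naive_best_in_neighborhood(inst$g, inst$s, m, "tbr", v = v)
      expect_identical(fast$best_cost, ref$best_cost)
      # leaf v: a single-node component has one rooting, so TBR = SPR
      if (is.na(inst$g$kid1[v]))
        expect_identical(fast$best_cost,
                         solve_r_sec(inst$g, inst$s, v, m)$best_cost)
    }
  }
})

test_that("TBR correction can strictly beat SPR correction", {
  # a corruption that only a rerooted regraft undoes: corrupt a congruent
  # gene tree by a TBR move with a genuine reroot and check the solvers
  s <- parse_newick("((((A,B),C),D),E);")
  found <- FALSE
  for (e in enumerate_tbr(s)) {
    if (e$edit$reroot_at == e$edit$pruned) next
    g <- e$tree
    tec <- solve_tec(g, s, "duploss")$best_cost
    sec <- solve_sec(g, s, "duploss")$best_cost
    expect_lte(tec, sec)
    expect_identical(tec, 0L)         # the inverse TBR is in the neighborhood
    if (sec > 0L) found <- TRUE
  }
  expect_true(found)
})

test_that("correction result invariants hold end to end", {
  for (i in 1:6) {
    inst <- rand_instance(7, seed = 2100 + i, dup = 0.2, nerr = 1)
    for (m in MODELS) {
      for (r in list(solve_sec(inst$g, inst$s, m), solve_tec(inst$g, inst$s, m))) {
        expect_lte(r$best_cost, r$original_cost)
        expect_identical(is.null(r$edit),
                         identical(write_newick(r$best_tree), write_newick(inst$g)))
        expect_identical(reconciliation_cost(r$best_tree, inst$s, m), r$best_cost)
        expect_valid_tree(r$best_tree)
      }
    }
  }
})
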