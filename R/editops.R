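# Tree edit operations: rerooting, SPR, TBR, NNI, and explicit neighborhood
# enumeration. All operations return fresh copies; surviving nodes keep
# their ids, and the vertex created by a subdivision inherits the id of the
# vertex suppressed by the paired contraction.

replace_child <- function(t, p, old, new) {
  if (t$kid1[p] == old) t$kid1[p] <- new else t$kid2[p] <- new
  t
}

#' Subtree prune and regraft
#'
#' Prunes the subtree rooted at `v` (suppressing its old parent) and
#' regrafts it on the edge above `y`; when `y` is the root of the remaining
#' component the subtree is attached above that root, creating a new root
#' (the planted-root position). The suppressed parent's id is reused for the
#' new attachment vertex, so the node-id set is unchanged.
#'
#' @param t An `rbtree` with at least 2 leaves.
#' @param v Node id of the subtree to prune (not the root).
#' @param y Regraft position: any node outside the pruned subtree other
#'   than `v`'s parent (which no longer bounds an edge once suppressed).
#' @return A new `rbtree`.
#' @examples
#' write_newick(spr(parse_newick("((A,C),B);"), 5L, 3L))  # prune B, regraft above A
#' @export
spr <- function(t, v, y) {
  u <- t$parent[v]
  if (is.na(u)) stop("cannot prune at the root")
  if (y == u) stop("regraft position was suppressed by the prune")
  inx <- preorder_nodes(t, v)
  if (y %in% inx) stop("regraft inside pruned subtree")
  w <- sibling_of(t, v)
  q <- t$parent[u]
  # detach v and suppress u
  if (is.na(q)) {
    t$root <- w; t$parent[w] <- NA_integer_
  } else {
    t <- replace_child(t, q, u, w); t$parent[w] <- q
  }
  # regraft above y, reusing slot u for the subdivision vertex
  py <- t$parent[y]
  if (is.na(py)) {
    t$kid1[u] <- y; t$kid2[u] <- v
    t$parent[y] <- u; t$parent[v] <- u
    t$parent[u] <- NA_integer_
    t$root <- u
  } else {
    t <- replace_child(t, py, y, u)
    t$parent[u] <- py
    t$kid1[u] <- y; t$kid2[u] <- v
    t$parent[y] <- u; t$parent[v] <- u
  }
  t
}

# Reroot the subtree hanging at r (possibly the whole tree) at x: suppress
# r's old position as subtree root and subdivide the edge above x, reusing
# r's slot as the new subtree root. Identity when x is r or a child of r.
rr_subtree <- function(t, r, x) {
  if (x == r || (!is.na(t$parent[x]) && t$parent[x] == r)) return(t)
  # path x < p1 < ... < pk, with pk a child of r
  path <- integer(0)
  p <- t$parent[x]
  while (!is.na(p) && p != r) { path <- c(path, p); p <- t$parent[p] }
  if (is.na(p)) stop("node is not inside the subtree being rerooted")
  k <- length(path)
  pk <- path[k]
  sib <- if (t$kid1[r] == pk) t$kid2[r] else t$kid1[r]
  # new root r: children (x, p1); chain reversal below
  prevs <- c(x, path)                      # prev[i] = vertex toward x from path[i]
  for (i in seq_len(k)) {
    pi <- path[i]
    nxt <- if (i < k) path[i + 1L] else sib
    t <- replace_child(t, pi, prevs[i], nxt)
    t$parent[nxt] <- pi
    t$parent[pi] <- if (i == 1L) r else path[i - 1L]
  }
  t$kid1[r] <- x; t$kid2[r] <- path[1L]
  t$parent[x] <- r
  t
}

#' Reroot a tree
#'
#' Moves the root onto the edge above `x`: the old root is suppressed and a
#' new root subdivides `(parent(x), x)`. Identity when `x` is the root or a
#' child of the root. The old root's id is reused for the new root.
#'
#' @param t An `rbtree` with at least 2 leaves.
#' @param x Node id in `t`.
#' @return A new `rbtree` over the same leaf multiset.
#' @examples
#' write_newick(reroot(parse_newick("((A,B),C);"), 3L))  # root above A
#' @export
reroot <- function(t, x) {
  if (n_leaves(t) < 2L) stop("reroot() needs a tree with >= 2 leaves")
  if (x < 1L || x > n_nodes(t)) stop("node not in tree")
  rr_subtree(t, t$root, x)
}

#' Tree bisection and reconnection
#'
#' Removes the edge above `v`, reroots the pruned component at `x`, and
#' regrafts it above `y` in the remaining component. `tbr(t, v, v, y)`
#' equals `spr(t, v, y)`.
#'
#' @param t An `rbtree`.
#' @param v Node id of the pruned subtree (not the root).
#' @param x Node id inside the pruned subtree (new rooting).
#' @param y Regraft position outside the pruned subtree.
#' @return A new `rbtree`.
#' @export
tbr <- function(t, v, x, y) {
  if (is.na(t$parent[v])) stop("cannot prune at the root")
  inx <- preorder_nodes(t, v)
  if (!(x %in% inx)) stop("rerooting node must lie inside the pruned subtree")
  if (y %in% inx) stop("regraft inside pruned subtree")
  t <- rr_subtree(t, v, x)
  spr(t, v, y)
}

#' Nearest neighbor interchange
#'
#' Prunes the subtree at `v` and regrafts it above its grandparent; when
#' `v`'s parent is the root the target is the planted-root position, so the
#' pruned subtree is re-attached above the remaining component's root.
#'
#' @param t An `rbtree`.
#' @param v Node id with a grandparent, or a child of the root.
#' @return A new `rbtree` equal to `spr(t, v, grandparent(v))`.
#' @export
nni <- function(t, v) {
  u <- t$parent[v]
  if (is.na(u)) stop("cannot apply NNI at the root")
  q <- t$parent[u]
  y <- if (is.na(q)) sibling_of(t, v) else q
  spr(t, v, y)
}

# Admissible regraft positions for pruning v: every node outside the
# pruned subtree except the suppressed parent; the remaining component's
# root denotes the planted-root position. Preorder of t for determinism.
spr_targets <- function(t, v) {
  u <- t$parent[v]
  if (is.na(u)) stop("cannot prune at the root")
  inx <- rep(FALSE, n_nodes(t))
  inx[preorder_nodes(t, v)] <- TRUE
  ord <- preorder_nodes(t)
  ord[!inx[ord] & ord != u]
}

new_edit <- function(kind, pruned, regraft, reroot_at = NA_integer_) {
  structure(list(kind = kind, pruned = as.integer(pruned),
                 reroot_at = as.integer(reroot_at),
                 regraft_above = as.integer(regraft)),
            class = "edit_descriptor")
}

#' @export
format.edit_descriptor <- function(x, ...) {
  if (x$kind == "TBR" && !is.na(x$reroot_at))
    sprintf("TBR prune=%d reroot=%d regraft=%d", x$pruned, x$reroot_at, x$regraft_above)
  else
    sprintf("%s prune=%d regraft=%d", x$kind, x$pruned, x$regraft_above)
}

#' @export
print.edit_descriptor <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Enumerate an SPR or TBR neighborhood
#'
#' Yields every tree obtainable by one SPR (or TBR) operation pruning at
#' `v` (or at every non-root vertex when `v` is `NULL`), exactly once per
#' coordinate pair; no isomorphism deduplication is performed, so the
#' neighborhood may contain trees isomorphic to the input (and, for TBR,
#' to each other).
#'
#' @param t An `rbtree` with at least 3 leaves.
#' @param v Node id to prune at, or `NULL` for all non-root vertices.
#' @return A list of entries `list(edit = <edit_descriptor>, tree = <rbtree>)`,
#'   in deterministic preorder-based order.
#' @export
enumerate_spr <- function(t, v = NULL) {
  vs <- if (is.null(v)) preorder_nodes(t)[-1L] else as.integer(v)
  out <- vector("list", 0L)
  for (vv in vs) {
    for (y in spr_targets(t, vv)) {
      out[[length(out) + 1L]] <-
        list(edit = new_edit("SPR", vv, y), tree = spr(t, vv, y))
    }
  }
  out
}

#' @rdname enumerate_spr
#' @export
enumerate_tbr <- function(t, v = NULL) {
  vs <- if (is.null(v)) preorder_nodes(t)[-1L] else as.integer(v)
  out <- vector("list", 0L)
  for (vv in vs) {
    xs <- preorder_nodes(t, vv)
    ys <- spr_targets(t, vv)
    for (x in xs) for (y in ys) {
      out[[length(out) + 1L]] <-
        list(edit = new_edit("TBR", vv, y, reroot_at = x),
             tree = tbr(t, vv, x, y))
    }
  }
  out
}
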