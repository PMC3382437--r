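# Constant-time LCA and depth queries via an Euler tour plus a sparse-table
# range-minimum structure (O(n log n) preprocessing, O(1) per query).

#' Build a constant-time LCA/depth index for a tree
#'
#' Preprocesses a tree so that least-common-ancestor, depth and path-length
#' queries answer in constant time. The structure is an Euler tour of the
#' tree with a sparse-table range-minimum index over tour depths.
#'
#' @param t An `rbtree`.
#' @return An object of class `lca_index`.
#' @examples
#' ix <- build_lca_index(parse_newick("((A,B),C);"))
#' lca(ix, 3L, 4L)    # the (A,B) ancestor
#' node_depth(ix, 3L)
#' @export
build_lca_index <- function(t) {
  n <- n_nodes(t)
  depth <- integer(n)
  ord <- preorder_nodes(t)
  for (v in ord[-1L]) depth[v] <- depth[t$parent[v]] + 1L

  # Euler tour: each internal vertex reappears after each child's tour
  len <- 2L * n - 1L
  euler <- integer(len); first <- integer(n)
  k <- 0L
  visit <- function(v) {
    k <<- k + 1L; euler[k] <<- v; first[v] <<- k
    if (!is.na(t$kid1[v])) {
      visit(t$kid1[v]); k <<- k + 1L; euler[k] <<- v
      visit(t$kid2[v]); k <<- k + 1L; euler[k] <<- v
    }
  }
  visit(t$root)
  ed <- depth[euler]

  K <- floor(log2(len)) + 1L
  st <- matrix(0L, nrow = len, ncol = K)   # st[i,k]: argmin position over euler[i .. i+2^(k-1)-1]
  st[, 1L] <- seq_len(len)
  if (K > 1L) {
    for (kk in 2:K) {
      half <- 2L^(kk - 2L)
      span <- len - 2L * half + 1L
      if (span < 1L) { st[, kk] <- st[, kk - 1L]; next }
      i <- seq_len(span)
      a <- st[i, kk - 1L]; b <- st[i + half, kk - 1L]
      st[i, kk] <- ifelse(ed[a] <= ed[b], a, b)
      if (span < len) st[(span + 1L):len, kk] <- st[(span + 1L):len, kk - 1L]
    }
  }
  lg <- integer(len)
  for (d in seq_len(len)) lg[d] <- floor(log2(d)) + 1L
  pow <- 2L^(seq_len(K) - 1L)

  structure(list(tree = t, depth = depth, euler = euler, first = first,
                 ed = ed, st = st, lg = lg, pow = pow),
            class = "lca_index")
}

#' Least common ancestor, depth and path-length queries
#'
#' `lca()` returns the least common ancestor of two nodes, `node_depth()`
#' the number of edges from the root, and `tree_dist()` the number of edges
#' on the path between two nodes
#' (`depth(x) + depth(y) - 2 * depth(lca(x, y))`). All vectorize over node
#' ids and run in constant time per query.
#'
#' @param ix An `lca_index` from [build_lca_index()].
#' @param u,v,x,y Node ids (vectors recycle).
#' @return Integer vector.
#' @export
lca <- function(ix, u, v) {
  ia <- ix$first[u]; ib <- ix$first[v]
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  k <- ix$lg[hi - lo + 1L]
  a <- ix$st[cbind(lo, k)]
  b <- ix$st[cbind(hi - ix$pow[k] + 1L, k)]
  ix$euler[ifelse(ix$ed[a] <= ix$ed[b], a, b)]
}

# scalar fast path used in inner loops
lca1 <- function(ix, u, v) {
  ia <- ix$first[u]; ib <- ix$first[v]
  if (ia > ib) { tmp <- ia; ia <- ib; ib <- tmp }
  k <- ix$lg[ib - ia + 1L]
  a <- ix$st[ia, k]
  b <- ix$st[ib - ix$pow[k] + 1L, k]
  if (ix$ed[a] <= ix$ed[b]) ix$euler[a] else ix$euler[b]
}

#' @rdname lca
#' @export
node_depth <- function(ix, v) ix$depth[v]

#' @rdname lca
#' @export
tree_dist <- function(ix, x, y) {
  ix$depth[x] + ix$depth[y] - 2L * ix$depth[lca(ix, x, y)]
}

#' @export
print.lca_index <- function(x, ...) {
  cat(sprintf("LCA index over a tree with %d nodes (Euler tour length %d)\n",
              n_nodes(x$tree), length(x$euler)))
  invisible(x)
}
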