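#' @keywords internal
"_PACKAGE"

# Rooted full binary trees ("rbtree") are stored as flat parallel vectors
# indexed by stable integer node ids assigned at parse time:
#   parent[v] : parent id, NA at the root
#   kid1[v], kid2[v] : child ids in written order, NA at leaves
#   label[v]  : leaf label, NA at internal nodes
#   root      : id of the root
# Edit operations reuse the id of any suppressed vertex for the vertex
# created by the paired subdivision, so ids survive rearrangement.

new_rbtree <- function(parent, kid1, kid2, label, root) {
  structure(
    list(parent = as.integer(parent), kid1 = as.integer(kid1),
         kid2 = as.integer(kid2), label = as.character(label),
         root = as.integer(root)),
    class = "rbtree"
  )
}

#' Number of nodes / leaves of a tree
#'
#' @param t An `rbtree`.
#' @return Integer count.
#' @export
n_nodes <- function(t) length(t$parent)

#' @rdname n_nodes
#' @export
n_leaves <- function(t) sum(!is.na(t$label))

#' Leaf node ids and labels
#'
#' @param t An `rbtree`.
#' @return `tree_leaves()` returns the integer ids of the leaves;
#'   `tree_labels()` their labels in the same order.
#' @export
tree_leaves <- function(t) which(!is.na(t$label))

#' @rdname tree_leaves
#' @export
tree_labels <- function(t) t$label[!is.na(t$label)]

is_leaf <- function(t, v) is.na(t$kid1[v])

sibling_of <- function(t, v) {
  u <- t$parent[v]
  if (is.na(u)) return(NA_integer_)
  if (t$kid1[u] == v) t$kid2[u] else t$kid1[u]
}

#' Preorder / postorder node ids
#'
#' Deterministic depth-first traversals in written child order, used as the
#' canonical iteration order throughout the package.
#'
#' @param t An `rbtree`.
#' @param from Node id to start from (default the root).
#' @return Integer vector of node ids.
#' @export
preorder_nodes <- function(t, from = t$root) {
  n <- n_nodes(t)
  out <- integer(n)
  stack <- integer(n)
  stack[1L] <- from
  top <- 1L
  k <- 0L
  k1 <- t$kid1; k2 <- t$kid2
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    k <- k + 1L; out[k] <- v
    if (!is.na(k1[v])) {
      top <- top + 1L; stack[top] <- k2[v]
      top <- top + 1L; stack[top] <- k1[v]
    }
  }
  out[seq_len(k)]
}

#' @rdname preorder_nodes
#' @export
postorder_nodes <- function(t, from = t$root) {
  rev(preorder_nodes_mirror(t, from))
}

# preorder visiting kid2 before kid1; its reverse is a valid postorder in
# written child order (children before parents, kid1 side first).
preorder_nodes_mirror <- function(t, from) {
  n <- n_nodes(t)
  out <- integer(n)
  stack <- integer(n)
  stack[1L] <- from
  top <- 1L
  k <- 0L
  k1 <- t$kid1; k2 <- t$kid2
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    k <- k + 1L; out[k] <- v
    if (!is.na(k1[v])) {
      top <- top + 1L; stack[top] <- k1[v]
      top <- top + 1L; stack[top] <- k2[v]
    }
  }
  out[seq_len(k)]
}

#' Node ids of the subtree rooted at a vertex
#'
#' @param t An `rbtree`.
#' @param v Node id.
#' @return Integer vector of ids (preorder, starting with `v`).
#' @export
subtree_nodes <- function(t, v) preorder_nodes(t, v)

#' Extract a subtree as a standalone tree
#'
#' Returns a compact copy of the subtree rooted at `v`, with fresh ids in
#' preorder.
#'
#' @param t An `rbtree`.
#' @param v Node id in `t`.
#' @return An `rbtree`.
#' @export
subtree_at <- function(t, v) {
  ids <- preorder_nodes(t, v)
  newid <- integer(n_nodes(t))
  newid[ids] <- seq_along(ids)
  m <- length(ids)
  par <- rep(NA_integer_, m); c1 <- rep(NA_integer_, m); c2 <- rep(NA_integer_, m)
  for (i in seq_along(ids)) {
    x <- ids[i]
    if (!is.na(t$kid1[x])) {
      c1[i] <- newid[t$kid1[x]]
      c2[i] <- newid[t$kid2[x]]
      par[c1[i]] <- i
      par[c2[i]] <- i
    }
  }
  new_rbtree(par, c1, c2, t$label[ids], 1L)
}

#' Parse a rooted Newick string
#'
#' Reads a single `;`-terminated rooted Newick expression into an `rbtree`.
#' Branch lengths and internal node labels are parsed and discarded; child
#' order is preserved as written. Node ids are assigned in preorder as the
#' string is read.
#'
#' Input must be strictly binary: any internal node with a number of
#' children other than two raises a "non-binary tree" error.
#'
#' @param text A single character string, e.g. `"((A,B),C);"`.
#' @return An `rbtree`.
#' @examples
#' t <- parse_newick("((A,B),C);")
#' n_nodes(t)
#' write_newick(t)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single character string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  keep <- !(chars %in% c(" ", "\t", "\n", "\r"))
  src <- chars[keep]
  posmap <- which(keep)              # original 1-based positions
  m <- length(src)
  if (m == 0L) stop("parse error at position 1: empty input")

  # growable node store (bounded by character count)
  cap <- max(3L, m)
  parent <- rep(NA_integer_, cap); kid1 <- rep(NA_integer_, cap)
  kid2 <- rep(NA_integer_, cap); label <- rep(NA_character_, cap)
  nn <- 0L
  i <- 1L

  pos_of <- function(j) if (j <= m) posmap[j] else posmap[m] + 1L
  fail <- function(j, msg) stop(sprintf("parse error at position %d: %s", pos_of(j), msg))

  new_node <- function() { nn <<- nn + 1L; nn }

  read_label <- function() {
    start <- i
    while (i <= m && !(src[i] %in% c("(", ")", ",", ":", ";"))) i <<- i + 1L
    if (i == start) return(NULL)
    paste(src[start:(i - 1L)], collapse = "")
  }

  skip_length <- function() {
    if (i <= m && src[i] == ":") {
      i <<- i + 1L
      start <- i
      while (i <= m && !(src[i] %in% c("(", ")", ",", ";"))) i <<- i + 1L
      if (i == start) fail(i, "expected a branch length after ':'")
    }
  }

  parse_subtree <- function() {
    if (i > m) fail(i, "unexpected end of input")
    if (src[i] == "(") {
      at <- i
      id <- new_node()
      i <<- i + 1L
      kids <- integer(0)
      repeat {
        kids <- c(kids, parse_subtree())
        if (i > m) fail(i, "unbalanced parentheses: missing ')'")
        if (src[i] == ",") { i <<- i + 1L; next }
        if (src[i] == ")") { i <<- i + 1L; break }
        fail(i, sprintf("unexpected character '%s'", src[i]))
      }
      if (length(kids) != 2L)
        stop(sprintf(
          "non-binary tree: internal node at position %d has %d children",
          pos_of(at), length(kids)))
      kid1[id] <<- kids[1L]; kid2[id] <<- kids[2L]
      parent[kids] <<- id
      read_label()      # internal label, discarded
      skip_length()     # branch length, discarded
      id
    } else {
      lab <- read_label()
      if (is.null(lab)) fail(i, sprintf("expected a leaf label, found '%s'",
                                        if (i <= m) src[i] else "end of input"))
      id <- new_node()
      label[id] <<- lab
      skip_length()
      id
    }
  }

  root <- parse_subtree()
  if (i > m || src[i] != ";") fail(i, "expected ';' terminating the tree")
  i <- i + 1L
  if (i <= m) fail(i, "trailing characters after ';'")

  new_rbtree(parent[seq_len(nn)], kid1[seq_len(nn)], kid2[seq_len(nn)],
             label[seq_len(nn)], root)
}

#' Write a tree as a Newick string
#'
#' Inverse of [parse_newick()] up to isomorphism; output carries no branch
#' lengths or internal labels.
#'
#' @param t An `rbtree`.
#' @return A single `;`-terminated character string.
#' @export
write_newick <- function(t) {
  rec <- function(v) {
    if (is.na(t$kid1[v])) t$label[v]
    else paste0("(", rec(t$kid1[v]), ",", rec(t$kid2[v]), ")")
  }
  paste0(rec(t$root), ";")
}

#' Read / write one-tree-per-line Newick files
#'
#' @param path File path.
#' @param trees A list of `rbtree` objects.
#' @return `read_newick_lines()` returns a list of `rbtree` objects.
#' @export
read_newick_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    out[[i]] <- tryCatch(parse_newick(lines[i]), error = function(e)
      stop(sprintf("line %d of '%s': %s", i, path, conditionMessage(e)), call. = FALSE))
  }
  out
}

#' @rdname read_newick_lines
#' @export
write_newick_lines <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

#' Canonical form of a tree
#'
#' A topology-identifying string: children are ordered by the
#' lexicographically smaller canonical substring, so two trees are
#' isomorphic (as rooted trees over leaf-label multisets) iff their
#' canonical forms are equal.
#'
#' @param t An `rbtree`.
#' @param v Root of the subtree to canonicalize (default the tree root).
#' @return A character string.
#' @export
canonical_form <- function(t, v = t$root) {
  if (is.na(t$kid1[v])) return(t$label[v])
  a <- canonical_form(t, t$kid1[v])
  b <- canonical_form(t, t$kid2[v])
  if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
}

#' Test whether two rooted trees are isomorphic
#'
#' Two trees are isomorphic when a bijection between their vertices matches
#' subtrees over identical leaf-label multisets; the test is insensitive to
#' child order and handles repeated labels.
#'
#' @param t1,t2 `rbtree` objects.
#' @return Logical.
#' @examples
#' is_isomorphic(parse_newick("((A,B),C);"), parse_newick("(C,(B,A));"))
#' @export
is_isomorphic <- function(t1, t2) {
  if (n_nodes(t1) != n_nodes(t2)) return(FALSE)
  identical(canonical_form(t1), canonical_form(t2))
}

# internal sanity check used by the test-suite helpers
validate_tree <- function(t) {
  n <- n_nodes(t)
  stopifnot(n >= 1L, t$root >= 1L, t$root <= n)
  internal <- !is.na(t$kid1)
  stopifnot(all(is.na(t$kid2[!internal])),
            all(!is.na(t$kid2[internal])),
            all(!is.na(t$label[!internal])),
            all(nzchar(t$label[!internal])),
            all(is.na(t$label[internal])))
  stopifnot(is.na(t$parent[t$root]), sum(is.na(t$parent)) == 1L)
  for (v in which(internal)) {
    stopifnot(t$parent[t$kid1[v]] == v, t$parent[t$kid2[v]] == v)
  }
  stopifnot(n == 2L * sum(!internal) - 1L)
  stopifnot(length(preorder_nodes(t)) == n)
  invisible(TRUE)
}

#' @export
print.rbtree <- function(x, ...) {
  nl <- n_leaves(x)
  cat(sprintf("Rooted binary tree: %d leaves, %d nodes\n", nl, n_nodes(x)))
  s <- write_newick(x)
  if (nchar(s) > 200) s <- paste0(substr(s, 1, 197), "...")
  cat(s, "\n")
  invisible(x)
}

#' Convert to an ape "phylo" object
#'
#' Convenience bridge to the wider R phylogenetics ecosystem (plotting,
#' distances, file formats). Requires the `ape` package and a tree with at
#' least two leaves.
#'
#' @param t An `rbtree`.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(t) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("as_phylo() requires the 'ape' package")
  if (n_leaves(t) < 2L) stop("as_phylo() needs a tree with >= 2 leaves")
  ape::read.tree(text = write_newick(t))
}
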