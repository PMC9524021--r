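# minimum spanning tree extraction: connectivity -> reciprocal weights ->
# Kruskal -> binarized tree

WEIGHT_CAP <- 1e12

#' Convert a correlation slice to edge weights
#'
#' Edge weight is the reciprocal of connection strength — the cost of
#' information exchange between two nodes. In the default `abs_reciprocal`
#' mode `w = 1/|c|`, so the strongest connections (of either sign) get the
#' smallest weights; `signed_reciprocal` takes the literal `w = 1/c`.
#' Correlations with `|c| < 1e-12` are mapped to the finite cap `1e12`.
#'
#' @param c_slice symmetric N x N correlation matrix (entries in [-1, 1]).
#' @param mode `"abs_reciprocal"` (default) or `"signed_reciprocal"`.
#' @return A `weight_matrix`: the N x N weight matrix with attribute `mode`;
#'   the diagonal is set to `Inf` and ignored downstream.
#' @export
weights_from_connectivity <- function(c_slice,
                                      mode = c("abs_reciprocal", "signed_reciprocal")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(c_slice), nrow(c_slice) == ncol(c_slice))
  if (any(abs(c_slice) > 1 + 1e-8, na.rm = TRUE)) {
    stopf("correlation entries must lie in [-1, 1]")
  }
  base <- if (mode == "abs_reciprocal") abs(c_slice) else c_slice
  near_zero <- abs(c_slice) < 1e-12
  w <- ifelse(near_zero, WEIGHT_CAP, 1 / base)
  if (any(near_zero[upper.tri(near_zero)])) {
    warnf("%d near-zero connection(s) capped at %g",
          sum(near_zero[upper.tri(near_zero)]), WEIGHT_CAP)
  }
  diag(w) <- Inf
  structure(w, mode = mode, class = c("weight_matrix", "matrix", "array"))
}

#' Construct a spanning tree object
#'
#' @param edges (n-1) x 2 integer matrix of node pairs.
#' @param n node count.
#' @param labels optional node labels.
#' @return An object of class `spanning_tree` with fields `n`, `edges`
#'   (each row ordered i < j) and the binarized `adjacency`.
#' @export
spanning_tree <- function(edges, n, labels = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (nrow(edges) != n - 1L) {
    stopf("a spanning tree on %d nodes needs exactly %d edges (got %d)",
          n, n - 1L, nrow(edges))
  }
  adj <- matrix(0L, n, n)
  adj[edges] <- 1L
  adj[edges[, c(2L, 1L), drop = FALSE]] <- 1L
  if (!is.null(labels)) dimnames(adj) <- list(labels, labels)
  # connectivity (and hence acyclicity, given n-1 edges) via BFS from node 1
  seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nb <- which(rowSums(adj[, frontier, drop = FALSE]) > 0L & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  if (!all(seen)) stopf("edge set does not span all %d nodes", n)
  structure(list(n = n, edges = edges, adjacency = adj),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("Spanning tree on %d nodes (%d edges)\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Minimum spanning tree by Kruskal's algorithm
#'
#' Ranks all node pairs from lowest to highest weight and adds them in order,
#' discarding any edge that would close a cycle, until all nodes are
#' connected. Ties are broken lexicographically by `(weight, i, j)` with
#' `i < j`, so the result is deterministic across platforms. The returned
#' tree is binarized: existing edges are 1, absent edges 0.
#'
#' @param weights symmetric N x N weight matrix (e.g. from
#'   [weights_from_connectivity()]); the diagonal is ignored.
#' @return A [spanning_tree].
#' @export
kruskal_mst <- function(weights) {
  w <- unclass(weights)
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  n <- nrow(w)
  if (n < 2L) stopf("need at least 2 nodes")
  idx <- which(upper.tri(w), arr.ind = TRUE)
  wv <- w[idx]
  if (any(!is.finite(wv))) stopf("non-finite edge weight(s) off the diagonal")
  ord <- order(wv, idx[, 1L], idx[, 2L])

  parent <- seq_len(n)
  find_root <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  edges <- matrix(0L, n - 1L, 2L)
  m <- 0L
  for (k in ord) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    ri <- find_root(i); rj <- find_root(j)
    if (ri != rj) {
      parent[ri] <- rj
      m <- m + 1L
      edges[m, ] <- c(i, j)
      if (m == n - 1L) break
    }
  }
  spanning_tree(edges, n, labels = rownames(w))
}

#' Total weight of a tree under a weight matrix
#'
#' @param tree a [spanning_tree].
#' @param weights the weight matrix the tree was built from.
#' @return Sum of the tree's edge weights.
#' @export
tree_weight <- function(tree, weights) {
  sum(unclass(weights)[tree$edges])
}

#' Minimum spanning trees for every time point of a connectivity tensor
#'
#' @param conn a [connectivity_tensor()] result, or a bare N x N x T array.
#' @param mode weight mode, see [weights_from_connectivity()].
#' @return An object of class `tree_series`: list of T [spanning_tree]s plus
#'   the subject id.
#' @export
tree_series <- function(conn, mode = c("abs_reciprocal", "signed_reciprocal")) {
  mode <- match.arg(mode)
  if (inherits(conn, "dcc_connectivity")) {
    tensor <- conn$tensor
    id <- conn$subject_id
  } else {
    tensor <- conn
    id <- "subject"
  }
  stopifnot(length(dim(tensor)) == 3L)
  t_len <- dim(tensor)[3L]
  trees <- vector("list", t_len)
  for (t in seq_len(t_len)) {
    trees[[t]] <- tryCatch(
      kruskal_mst(weights_from_connectivity(tensor[, , t], mode = mode)),
      error = function(e) stopf("time point %d: %s", t, conditionMessage(e)))
  }
  structure(list(trees = trees, subject_id = id), class = "tree_series")
}

#' @export
print.tree_series <- function(x, ...) {
  cat(sprintf("Tree series for '%s': %d trees on %d nodes\n",
              x$subject_id, length(x$trees), x$trees[[1L]]$n))
  invisible(x)
}

#' @export
length.tree_series <- function(x) length(x$trees)
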