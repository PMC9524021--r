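# independent brute-force oracles used to validate the tree algorithms

# decode a Pruefer sequence into the (n-1) x 2 edge matrix of its tree
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 0L
  for (i in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, seq[i])
    degree[leaf] <- 0L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

# exhaustive minimum spanning-tree weight over all n^(n-2) labelled trees
enumerate_min_tree_weight <- function(w) {
  n <- nrow(w)
  if (n == 2L) return(w[1L, 2L])
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (k in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[k, ], n)
    tw <- sum(w[e])
    if (tw < best) best <- tw
  }
  best
}

random_tree <- function(n) {
  if (n == 2L) return(spanning_tree(matrix(c(1L, 2L), 1L), 2L))
  spanning_tree(prufer_decode(sample.int(n, n - 2L, replace = TRUE), n), n)
}

path_tree <- function(n) spanning_tree(cbind(1:(n - 1L), 2:n), n)
star_tree <- function(n, hub = 1L) {
  spanning_tree(cbind(hub, setdiff(seq_len(n), hub)), n)
}

# all-pairs hop distances by Floyd-Warshall (independent of the package BFS)
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0L, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# betweenness oracle: v lies on the unique s-t path iff d(s,v)+d(v,t)=d(s,t)
oracle_node_metrics <- function(tree) {
  adj <- tree$adjacency
  n <- nrow(adj)
  d <- fw_distances(adj)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    cnt <- 0L
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        if (s == v || t == v) next
        if (d[s, v] + d[v, t] == d[s, t]) cnt <- cnt + 1L
      }
    }
    bc[v] <- cnt / ((n - 1) * (n - 2) / 2)
  }
  up <- upper.tri(d)
  list(degree = as.integer(rowSums(adj)),
       betweenness = bc,
       eccentricity = as.integer(apply(d, 1L, max)),
       diameter = max(d),
       global_efficiency = mean(1 / d[up]),
       char_path_length = mean(d[up]))
}

# random symmetric weight matrix with all-distinct off-diagonal entries
random_weights <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, 0.1, 10)
  w <- w + t(w)
  diag(w) <- Inf
  w
}
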