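# per-tree node- and network-level parameters, and their per-subject
# temporal summaries

NETWORK_METRICS <- c("k_max", "leaf_fraction", "assortativity", "diameter",
                     "bc_max", "global_efficiency", "char_path_length",
                     "degree_divergence", "tree_hierarchy")
NODE_METRICS <- c("degree", "betweenness", "eccentricity")

# hop-count distance matrix of a tree by BFS from every node
tree_distances <- function(adj) {
  n <- nrow(adj)
  nb <- apply(adj > 0L, 1L, which, simplify = FALSE)
  d <- matrix(0L, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[dist[nxt] < 0L]
      dist[nxt] <- dist[frontier[1L]] + 1L
      # all frontier nodes share a distance in BFS from a single source
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

# component sizes of the forest obtained by deleting node v from the tree
component_sizes_without <- function(edges, n, v) {
  keep <- edges[edges[, 1L] != v & edges[, 2L] != v, , drop = FALSE]
  parent <- seq_len(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(keep))) {
    a <- find_root(keep[k, 1L]); b <- find_root(keep[k, 2L])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n)[-v], find_root, 0L)
  as.integer(table(roots))
}

#' Node-level parameters of a spanning tree
#'
#' Computes, for every node: its degree (edge count); its normalized
#' betweenness centrality — the number of unordered node pairs, neither of
#' them the node itself, whose unique tree path passes through the node,
#' divided by `(N-1)(N-2)/2` so that the hub of a star scores exactly 1; and
#' its eccentricity — the maximum hop distance to any other node.
#'
#' @param tree a [spanning_tree].
#' @return A `node_metrics` object: list with integer vector `degree`,
#'   numeric `betweenness` in [0, 1] and integer `eccentricity`, plus
#'   `labels`.
#' @export
node_metrics <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  n <- tree$n
  adj <- tree$adjacency
  degree <- as.integer(rowSums(adj))
  d <- tree_distances(adj)
  ecc <- as.integer(apply(d, 1L, max))
  denom <- (n - 1) * (n - 2) / 2
  bc <- vapply(seq_len(n), function(v) {
    if (degree[v] <= 1L) return(0)  # leaves separate nothing
    cs <- component_sizes_without(tree$edges, n, v)
    (((n - 1)^2 - sum(cs^2)) / 2) / denom
  }, 0)
  structure(list(degree = degree, betweenness = bc, eccentricity = ecc,
                 labels = rownames(adj) %||% sprintf("n%02d", seq_len(n)),
                 distances = d),
            class = "node_metrics")
}

#' Network-level parameters of a spanning tree
#'
#' Computes the tree-level summary of the node metrics: maximum degree `K`;
#' leaf number and leaf fraction `L / (N-1)`; degree assortativity (Pearson
#' correlation over the `2(N-1)` directed edge-endpoint degree pairs, `NA`
#' when the endpoint degrees are constant — a star is maximally
#' disassortative, exactly -1, under this formulation); diameter; maximum
#' betweenness `BC`; global efficiency (mean of `1/d` over unordered pairs);
#' characteristic path length (mean of `d` over unordered pairs); degree
#' divergence `<k^2>/<k>`; and tree hierarchy `L / (2 (N-1) BC)`.
#'
#' @param tree a [spanning_tree].
#' @param node_m optional precomputed [node_metrics()] for `tree`.
#' @return A named numeric vector of class `tree_metrics` with elements
#'   `k_max`, `leaf_number`, `leaf_fraction`, `assortativity`, `diameter`,
#'   `bc_max`, `global_efficiency`, `char_path_length`, `degree_divergence`,
#'   `tree_hierarchy`.
#' @export
tree_metrics <- function(tree, node_m = node_metrics(tree)) {
  n <- tree$n
  k <- node_m$degree
  d <- node_m$distances
  up <- upper.tri(d)
  leaf_number <- sum(k == 1L)
  bc_max <- max(node_m$betweenness)
  # degrees at both ends of every edge, both directions
  ends <- rbind(tree$edges, tree$edges[, c(2L, 1L)])
  k1 <- k[ends[, 1L]]; k2 <- k[ends[, 2L]]
  assort <- if (stats::sd(k1) < 1e-12 || stats::sd(k2) < 1e-12) NA_real_
            else stats::cor(k1, k2)
  out <- c(k_max = max(k),
           leaf_number = leaf_number,
           leaf_fraction = leaf_number / (n - 1),
           assortativity = assort,
           diameter = max(d),
           bc_max = bc_max,
           global_efficiency = mean(1 / d[up]),
           char_path_length = mean(d[up]),
           degree_divergence = mean(k^2) / mean(k),
           tree_hierarchy = leaf_number / (2 * (n - 1) * bc_max))
  class(out) <- c("tree_metrics", "numeric")
  out
}

#' @export
print.tree_metrics <- function(x, digits = 4, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Metric time courses of a tree series
#'
#' Evaluates [node_metrics()] and [tree_metrics()] independently at every
#' time point. Undefined assortativity values (star-shaped trees) are kept
#' as `NA`, never coerced to zero.
#'
#' @param ts a [tree_series].
#' @return A `metric_timecourses` object: list with `network` (T x 10 data
#'   frame, including `leaf_number`), `node` (list of three T x N matrices
#'   `degree`, `betweenness`, `eccentricity`), `labels` and `subject_id`.
#' @export
metric_timecourses <- function(ts) {
  stopifnot(inherits(ts, "tree_series"))
  t_len <- length(ts$trees)
  if (!t_len) stopf("empty tree series")
  n <- ts$trees[[1L]]$n
  nm1 <- node_metrics(ts$trees[[1L]])
  labels <- nm1$labels

  net <- matrix(NA_real_, t_len, 10L)
  deg <- matrix(NA_integer_, t_len, n)
  btw <- matrix(NA_real_, t_len, n)
  ecc <- matrix(NA_integer_, t_len, n)
  for (t in seq_len(t_len)) {
    nm <- if (t == 1L) nm1 else node_metrics(ts$trees[[t]])
    tm <- tree_metrics(ts$trees[[t]], nm)
    net[t, ] <- unclass(tm)
    deg[t, ] <- nm$degree
    btw[t, ] <- nm$betweenness
    ecc[t, ] <- nm$eccentricity
  }
  net <- as.data.frame(net)
  names(net) <- c("k_max", "leaf_number", "leaf_fraction", "assortativity",
                  "diameter", "bc_max", "global_efficiency",
                  "char_path_length", "degree_divergence", "tree_hierarchy")
  colnames(deg) <- colnames(btw) <- colnames(ecc) <- labels
  structure(list(network = net,
                 node = list(degree = deg, betweenness = btw, eccentricity = ecc),
                 labels = labels, subject_id = ts$subject_id),
            class = "metric_timecourses")
}

#' @export
print.metric_timecourses <- function(x, ...) {
  cat(sprintf("Metric time courses for '%s': T = %d, %d nodes\n",
              x$subject_id, nrow(x$network), length(x$labels)))
  invisible(x)
}

#' Temporal mean and variance of every tree parameter
#'
#' Reduces the per-timepoint metric courses of one subject to their temporal
#' mean and temporal variance: one row for each of the 9 network-level
#' parameters and each of the 3 node-level parameters per node
#' (`degree_<label>`, `betweenness_<label>`, `eccentricity_<label>`). Time
#' points with missing values (undefined assortativity) are excluded from
#' that metric's summaries, with the retained count reported in `n_used`.
#'
#' @param tc a [metric_timecourses] object.
#' @param var_estimator `"sample"` (default; divisor `n-1`) or `"population"`
#'   (divisor `n`).
#' @return A `subject_summary` data frame with columns `metric`,
#'   `temporal_mean`, `temporal_variance`, `n_used`, and attribute
#'   `subject_id`.
#' @export
temporal_summaries <- function(tc, var_estimator = c("sample", "population")) {
  stopifnot(inherits(tc, "metric_timecourses"))
  var_estimator <- match.arg(var_estimator)
  t_len <- nrow(tc$network)
  if (t_len < 2L) stopf("need at least 2 time points to form temporal variances")

  one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      return(c(mean = NA_real_, variance = NA_real_, n = length(v)))
    }
    vr <- stats::var(v)
    if (var_estimator == "population") vr <- vr * (length(v) - 1) / length(v)
    c(mean = mean(v), variance = vr, n = length(v))
  }

  cols <- c(as.list(tc$network[NETWORK_METRICS]),
            stats::setNames(
              unlist(lapply(NODE_METRICS, function(m) {
                lapply(seq_along(tc$labels), function(i) tc$node[[m]][, i])
              }), recursive = FALSE),
              unlist(lapply(NODE_METRICS, function(m) paste0(m, "_", tc$labels)))))
  res <- t(vapply(cols, one, c(mean = 0, variance = 0, n = 0)))
  out <- data.frame(metric = names(cols), temporal_mean = res[, "mean"],
                    temporal_variance = res[, "variance"],
                    n_used = as.integer(res[, "n"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("subject_summary", "data.frame"),
            subject_id = tc$subject_id, var_estimator = var_estimator)
}

#' Stack per-subject summaries into a wide cohort table
#'
#' @param summaries list of `subject_summary` objects (one per subject).
#' @return A data frame with one row per subject: `subject_id`, then
#'   `mean_<metric>` and `var_<metric>` columns.
#' @export
cohort_summaries <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "subject_summary"))
    vals <- c(stats::setNames(s$temporal_mean, paste0("mean_", s$metric)),
              stats::setNames(s$temporal_variance, paste0("var_", s$metric)))
    cbind(data.frame(subject_id = attr(s, "subject_id"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
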