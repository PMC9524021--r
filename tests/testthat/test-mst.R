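# reciprocal weights and Kruskal minimum spanning trees

test_that("reciprocal weights follow the mode rules and cap", {
  c_slice <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0, -0.5, 0, 1), 3, 3)
  expect_warning(w_abs <- weights_from_connectivity(c_slice), "capped")
  expect_equal(w_abs[1, 2], 2.0)
  expect_equal(w_abs[1, 3], 2.0)       # |-0.5| -> 2
  expect_equal(w_abs[2, 3], 1e12)      # zero correlation capped

  w_sgn <- suppressWarnings(
    weights_from_connectivity(c_slice, mode = "signed_reciprocal"))
  expect_equal(w_sgn[1, 3], -2.0)
  expect_error(weights_from_connectivity(matrix(2, 2, 2)), "\\[-1, 1\\]")
})

test_that("the K4 example tree is found with total weight 6", {
  # weights AB:1 AC:2 AD:5 BC:4 BD:3 CD:6
  w <- matrix(Inf, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 2
  w[1, 4] <- w[4, 1] <- 5
  w[2, 3] <- w[3, 2] <- 4
  w[2, 4] <- w[4, 2] <- 3
  w[3, 4] <- w[4, 3] <- 6
  tree <- kruskal_mst(w)
  expect_equal(tree$edges, rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L)),
               ignore_attr = TRUE)
  expect_equal(tree_weight(tree, w), 6)
})

test_that("random 18-node trees have exactly 17 edges, connected, acyclic", {
  set.seed(23)
  for (i in 1:10) {
    tree <- kruskal_mst(random_weights(18))
    expect_equal(nrow(tree$edges), 17L)
    expect_equal(sum(tree$adjacency), 2L * 17L)  # binarized, symmetric
    expect_true(all(tree$adjacency %in% c(0L, 1L)))
    # spanning_tree() itself validates connectivity; reaching here means both
    d <- fw_distances(tree$adjacency)
    expect_true(all(is.finite(d)))
  }
})

test_that("Kruskal matches exhaustive enumeration on small graphs", {
  set.seed(29)
  for (i in 1:30) {
    n <- sample(4:7, 1)
    w <- random_weights(n)
    expect_equal(tree_weight(kruskal_mst(w), w), enumerate_min_tree_weight(w),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (i in 1:10) {
    w <- random_weights(18)
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(is.finite(w), w, 0), mode = "undirected", weighted = TRUE)
    ig_w <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(tree_weight(kruskal_mst(w), w), ig_w, tolerance = 1e-9)
  }
})

test_that("tie-breaking is deterministic and order decides the tree", {
  w <- matrix(1, 5, 5); diag(w) <- Inf
  t1 <- kruskal_mst(w)
  t2 <- kruskal_mst(w)
  expect_identical(t1$edges, t2$edges)
  # all-equal weights with (i, j) tie-break picks the lexicographic star
  expect_equal(t1$edges, cbind(1L, 2:5), ignore_attr = TRUE)

  # monotone transform of the weights preserves the edge set
  set.seed(37)
  w2 <- random_weights(10)
  a <- kruskal_mst(w2)$edges
  b <- kruskal_mst(exp(w2 / 3))$edges
  expect_identical(a, b)
})

test_that("a tree is built per time point and dominant edges persist", {
  set.seed(41)
  n <- 5; t_len <- 100
  tensor <- array(0.1, c(n, n, t_len))
  tensor <- tensor + array(runif(n * n * t_len, 0, 0.2), c(n, n, t_len))
  for (t in seq_len(t_len)) {
    sl <- (tensor[, , t] + t(tensor[, , t])) / 2
    sl[1, 2] <- sl[2, 1] <- 0.95      # always the strongest connection
    diag(sl) <- 1
    tensor[, , t] <- sl
  }
  ts <- tree_series(tensor)
  expect_length(ts, t_len)
  expect_true(all(vapply(ts$trees, function(tr) tr$adjacency[1, 2] == 1L, NA)))

  # a time-constant tensor yields identical trees
  const <- array(rep(tensor[, , 1], t_len), c(n, n, t_len))
  tsc <- tree_series(const)
  expect_true(all(vapply(tsc$trees, function(tr) {
    identical(tr$edges, tsc$trees[[1]]$edges)
  }, NA)))
})
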