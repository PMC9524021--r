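# node- and network-level tree parameters and their temporal summaries

test_that("star topology: closed-form parameter values on 18 nodes", {
  tree <- star_tree(18)
  nm <- node_metrics(tree)
  expect_equal(nm$degree[1], 17L)
  expect_equal(nm$betweenness[1], 1.0)         # hub separates all pairs
  expect_equal(nm$eccentricity[1], 1L)
  expect_equal(nm$eccentricity[-1], rep(2L, 17))
  expect_equal(nm$betweenness[-1], rep(0, 17))

  tm <- tree_metrics(tree, nm)
  expect_equal(tm[["leaf_number"]], 17)
  expect_equal(tm[["leaf_fraction"]], 1.0)
  expect_equal(tm[["diameter"]], 2)
  expect_equal(tm[["k_max"]], 17)
  expect_equal(tm[["tree_hierarchy"]], 0.5)            # 17 / (2 * 17 * 1)
  expect_equal(tm[["degree_divergence"]], 9.0)
  expect_equal(tm[["global_efficiency"]], 85 / 153)
  expect_equal(tm[["char_path_length"]], 289 / 153)
  # directed edge-endpoint pairs make the star maximally disassortative
  expect_equal(tm[["assortativity"]], -1)
})

test_that("path topology: closed-form parameter values on 18 nodes", {
  tree <- path_tree(18)
  nm <- node_metrics(tree)
  expect_equal(sum(nm$degree == 1L), 2L)
  expect_equal(nm$eccentricity[1], 17L)
  expect_equal(max(nm$betweenness), 72 / 136)  # positions 9 and 10
  expect_equal(which(nm$betweenness == max(nm$betweenness)), c(9L, 10L))

  tm <- tree_metrics(tree, nm)
  expect_equal(tm[["leaf_number"]], 2)
  expect_equal(tm[["diameter"]], 17)
  expect_equal(tm[["tree_hierarchy"]], 2 / (2 * 17 * (72 / 136)))
  expect_equal(tm[["degree_divergence"]], 66 / 34)
})

test_that("metrics match the brute-force oracle on random small trees", {
  set.seed(43)
  for (i in 1:30) {
    n <- sample(4:7, 1)
    tree <- random_tree(n)
    nm <- node_metrics(tree)
    tm <- tree_metrics(tree, nm)
    or <- oracle_node_metrics(tree)
    expect_equal(nm$degree, or$degree)
    expect_equal(nm$betweenness, or$betweenness, tolerance = 1e-12)
    expect_equal(nm$eccentricity, or$eccentricity)
    expect_equal(tm[["diameter"]], or$diameter)
    expect_equal(tm[["global_efficiency"]], or$global_efficiency, tolerance = 1e-12)
    expect_equal(tm[["char_path_length"]], or$char_path_length, tolerance = 1e-12)
  }
})

test_that("tree invariants hold on random trees", {
  set.seed(47)
  for (i in 1:20) {
    n <- sample(3:18, 1)
    tree <- random_tree(n)
    nm <- node_metrics(tree)
    tm <- tree_metrics(tree, nm)
    expect_equal(sum(nm$degree), 2L * (n - 1L))          # handshake
    expect_gte(tm[["leaf_number"]], 2)
    if (n >= 3) expect_gte(tm[["diameter"]], 2)
    expect_lte(tm[["bc_max"]], 1)
    expect_lte(tm[["global_efficiency"]], 1)
    expect_gte(tm[["char_path_length"]], 1)
    # identity defining tree hierarchy
    expect_equal(tm[["tree_hierarchy"]] * 2 * (n - 1) * tm[["bc_max"]],
                 tm[["leaf_number"]], tolerance = 1e-12)
    if (!is.na(tm[["assortativity"]])) {
      expect_gte(tm[["assortativity"]], -1)
      expect_lte(tm[["assortativity"]], 1)
    }
  }
})

test_that("metric time courses are computed independently per time point", {
  n <- 18
  trees <- rep(list(star_tree(n), path_tree(n)), 5)
  ts <- structure(list(trees = trees, subject_id = "alt"), class = "tree_series")
  tc <- metric_timecourses(ts)
  expect_equal(nrow(tc$network), 10L)
  expect_equal(tc$network$diameter, rep(c(2, 17), 5))
  expect_equal(tc$network$leaf_number, rep(c(17, 2), 5))
  expect_equal(unname(rowSums(tc$node$degree)), rep(2 * (n - 1), 10))
  expect_equal(tc$network$assortativity[c(TRUE, FALSE)], rep(-1, 5))
  expect_false(anyNA(tc$network$assortativity))
})

test_that("temporal summaries reduce courses to mean and variance", {
  trees <- rep(list(star_tree(6)), 10)
  ts <- structure(list(trees = trees, subject_id = "const"),
                  class = "tree_series")
  s <- temporal_summaries(metric_timecourses(ts))
  expect_s3_class(s, "subject_summary")
  # 9 network + 3 x 6 node metrics
  expect_equal(nrow(s), 9L + 18L)
  expect_true(all(s$temporal_variance == 0))
  expect_equal(s$temporal_mean[s$metric == "assortativity"], -1)

  # undefined assortativity (two-node trees have constant endpoint degrees)
  ts2 <- structure(list(trees = rep(list(path_tree(2)), 5), subject_id = "p2"),
                   class = "tree_series")
  s_na <- temporal_summaries(metric_timecourses(ts2))
  expect_true(is.na(s_na$temporal_mean[s_na$metric == "assortativity"]))
  expect_equal(s_na$n_used[s_na$metric == "assortativity"], 0L)

  # arithmetic spot check on a hand-made course
  tc <- metric_timecourses(structure(
    list(trees = list(star_tree(4), path_tree(4), star_tree(4)),
         subject_id = "x"), class = "tree_series"))
  s2 <- temporal_summaries(tc)
  leaf <- tc$network$leaf_number                 # 3, 2, 3
  row <- s2[s2$metric == "leaf_fraction", ]
  expect_equal(row$temporal_mean, mean(leaf / 3))
  expect_equal(row$temporal_variance, var(leaf / 3))
  # population-variance option
  s3 <- temporal_summaries(tc, var_estimator = "population")
  row3 <- s3[s3$metric == "leaf_fraction", ]
  expect_equal(row3$temporal_variance, var(leaf / 3) * 2 / 3)
})

test_that("time-constant connectivity gives near-zero temporal variances", {
  sp <- cohort_spec(n_per_group = c(ASD = 0, TD = 1), n_nodes = 5,
                    t_len = 120, theta1 = 0, theta2 = 0, seed = 99)
  sim <- simulate_dcc_cohort(sp)
  # theta = 0 truth: constant R_t; estimated tensors wobble slightly, so
  # build trees from the true constant correlations instead
  qb <- sim$truth$spec$qbar * sim$truth$subjects[[1]]$qbar_scale
  diag(qb) <- 1
  tensor <- array(rep(qb, 120), c(5, 5, 120))
  s <- temporal_summaries(metric_timecourses(tree_series(tensor)))
  bounded <- s[s$metric %in% c("leaf_fraction", "bc_max", "global_efficiency",
                               "tree_hierarchy"), ]
  expect_true(all(bounded$temporal_variance < 0.01))
})

test_that("cohort summary table is one wide row per subject", {
  trees <- list(star_tree(4), path_tree(4))
  mk <- function(id) {
    tc <- metric_timecourses(structure(list(trees = trees, subject_id = id),
                                       class = "tree_series"))
    temporal_summaries(tc)
  }
  wide <- cohort_summaries(list(mk("a"), mk("b")))
  expect_equal(nrow(wide), 2L)
  expect_equal(wide$subject_id, c("a", "b"))
  expect_true(all(c("mean_global_efficiency", "var_degree_n01") %in% names(wide)))
  expect_equal(ncol(wide), 1L + 2L * (9L + 12L))
})
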