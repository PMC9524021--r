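# the synthetic DCC-GARCH generator: stationary laws, reproducibility,
# group effects, and correlation-matrix validity

test_that("GARCH generator matches its stationary variance", {
  # alpha = beta = 0 reduces to i.i.d. N(0, omega)
  y <- simulate_garch_series(1, 0, 0, 20000, seed = 5)
  expect_lt(abs(var(y) - 1), 0.05)

  # unconditional variance omega / (1 - alpha - beta) = 1
  y2 <- simulate_garch_series(0.1, 0.1, 0.8, 50000, seed = 6)
  expect_lt(abs(var(y2) - 1), 0.10)

  expect_identical(simulate_garch_series(0.1, 0.1, 0.8, 100, seed = 7),
                   simulate_garch_series(0.1, 0.1, 0.8, 100, seed = 7))
  expect_error(simulate_garch_series(0.1, 0.5, 0.5, 100), "alpha \\+ beta")
  expect_error(simulate_garch_series(-1, 0.1, 0.1, 100), "omega")
})

test_that("static-correlation limit reproduces the long-run matrix", {
  # theta1 = theta2 = 0: R_t == qbar, so realized windowed correlations sit
  # at the qbar entry up to sampling error
  sp <- cohort_spec(n_per_group = c(ASD = 0, TD = 1), n_nodes = 3,
                    t_len = 2000, theta1 = 0, theta2 = 0,
                    qbar_structure = "exchangeable", qbar_offdiag = 0.5,
                    base_qbar_scale = 1, subject_qbar_sd = 0, seed = 21)
  sim <- simulate_dcc_cohort(sp)
  y <- sim$series[[1]]$data
  for (w in list(1:500, 501:1000, 1001:1500, 1501:2000)) {
    cc <- cor(t(y[, w]))
    off <- cc[upper.tri(cc)]
    expect_true(all(abs(off - 0.5) < 0.15))
  }
})

test_that("identical seeds give bit-identical cohorts", {
  sp <- cohort_spec(n_per_group = c(ASD = 2, TD = 2), t_len = 100, seed = 33)
  a <- simulate_dcc_cohort(sp)
  b <- simulate_dcc_cohort(sp)
  expect_identical(lapply(a$series, `[[`, "data"),
                   lapply(b$series, `[[`, "data"))
  expect_identical(a$cohort$records, b$cohort$records)
})

test_that("patient-group scaling lowers realized pairwise correlation", {
  sp <- cohort_spec(n_per_group = c(ASD = 20, TD = 20), t_len = 300,
                    group_qbar_scale = 0.5, seed = 44)
  sim <- simulate_dcc_cohort(sp)
  grp <- sim$cohort$records$group
  mean_abs_cor <- vapply(sim$series, function(ts) {
    cc <- cor(t(ts$data))
    mean(abs(cc[upper.tri(cc)]))
  }, 0)
  expect_lt(mean(mean_abs_cor[grp == "ASD"]), mean(mean_abs_cor[grp == "TD"]))
})

test_that("generated correlation matrices are valid at every time point", {
  sp <- cohort_spec(n_per_group = c(ASD = 1, TD = 1), t_len = 150, seed = 55)
  sim <- simulate_dcc_cohort(sp, keep_rt = TRUE)
  for (s in sim$truth$subjects) {
    rt <- s$rt
    for (t in seq(1, dim(rt)[3], by = 10)) {
      R <- rt[, , t]
      expect_equal(diag(R), rep(1, nrow(R)))
      expect_equal(R, t(R))
      expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    }
  }
})

test_that("zero ADOS coupling leaves scores unrelated to connectivity", {
  sp <- cohort_spec(n_per_group = c(ASD = 60, TD = 0), t_len = 100,
                    ados_coupling = list(node = 1, coef = 0), seed = 66)
  sim <- simulate_dcc_cohort(sp)
  conn <- vapply(sim$truth$subjects, function(s) mean(s$mean_r[1, -1]), 0)
  ados <- sim$cohort$records$ados_total
  expect_lt(abs(cor(conn, ados)), 0.3)  # 95% null bound ~ 0.25 at n = 60
})

test_that("infeasible specs are rejected up front", {
  expect_error(cohort_spec(theta1 = 0.2, theta2 = 0.85), "theta1")
  expect_error(cohort_spec(theta1 = 0.1, theta2 = 0.85, group_theta_shift = 0.1),
               "group_theta_shift")
  expect_error(cohort_spec(group_qbar_scale = 0), "group_qbar_scale")
  bad_qbar <- matrix(0.99, 4, 4); diag(bad_qbar) <- c(1, 1, 1, -1)
  expect_error(cohort_spec(n_nodes = 4, qbar = bad_qbar), "positive definite")
})
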