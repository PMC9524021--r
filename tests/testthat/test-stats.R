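# covariate-adjusted group tests, FDR, and symptom correlations

# a well-behaved synthetic cohort + summary table without running the
# estimation pipeline: summaries drawn around group means with known shift
stats_fixture <- function(n_per_group = 30, shift = 0, seed = 1,
                          sites = c("SITE_A", "SITE_B")) {
  set.seed(seed)
  n <- 2 * n_per_group
  rec <- data.frame(
    subject_id = sprintf("p%03d", 1:n),
    group = rep(c("ASD", "TD"), each = n_per_group),
    age = rnorm(n, 16, 5),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.8, 0.2)),
    iq = round(rnorm(n, 108, 12)),
    site = rep_len(sites, n),
    func_mean_fd = runif(n, 0.02, 0.18),
    func_perc_fd = runif(n, 0, 20),
    ados_total = c(round(runif(n_per_group, 8, 20)), rep(NA, n_per_group)),
    ados_comm = c(round(runif(n_per_group, 2, 8)), rep(NA, n_per_group)),
    ados_social = c(round(runif(n_per_group, 4, 12)), rep(NA, n_per_group)),
    ados_stereo_behav = c(round(runif(n_per_group, 0, 4)), rep(NA, n_per_group)),
    stringsAsFactors = FALSE)
  summaries <- data.frame(
    subject_id = rec$subject_id,
    mean_global_efficiency = rnorm(n, 0.6, 0.05) +
      ifelse(rec$group == "ASD", shift, 0),
    var_global_efficiency = abs(rnorm(n, 3e-4, 1e-4)),
    mean_degree_n01 = rnorm(n, 2.5, 0.4),
    var_degree_n01 = abs(rnorm(n, 0.5, 0.1)),
    mean_degree_n02 = rnorm(n, 2.0, 0.4),
    var_degree_n02 = abs(rnorm(n, 0.5, 0.1)),
    stringsAsFactors = FALSE)
  list(cohort = cohort(rec), summaries = summaries)
}

test_that("design matrix coding: intercept, group, sex, reference-coded site", {
  fx <- stats_fixture()
  X <- build_design(fx$cohort)
  expect_true(all(c("(Intercept)", "group_ASD", "age", "iq", "func_mean_fd",
                    "func_perc_fd") %in% colnames(X)))
  expect_equal(sum(startsWith(colnames(X), "site_")), 1L)  # 2 sites -> 1 column
  expect_equal(sum(startsWith(colnames(X), "sex_")), 1L)
  expect_equal(nrow(X), 60L)

  # missing IQ drops the subject and logs it
  fx2 <- stats_fixture()
  fx2$cohort$records$iq[5] <- NA
  X2 <- build_design(fx2$cohort)
  expect_equal(nrow(X2), 59L)
  expect_equal(attr(X2, "dropped"), "p005")

  # single site: columns omitted with a warning
  fx3 <- stats_fixture(sites = "ONLY")
  expect_warning(X3 <- build_design(fx3$cohort), "single-site")
  expect_false(any(startsWith(colnames(X3), "site_")))
})

test_that("a site perfectly aligned with group triggers a rank error", {
  fx <- stats_fixture()
  fx$cohort$records$site <- ifelse(fx$cohort$records$group == "ASD",
                                   "SITE_ASD", "SITE_TD")
  expect_error(build_design(fx$cohort), "rank deficient")
})

test_that("with no covariates the adjusted test equals the pooled t-test", {
  fx <- stats_fixture(shift = 0.03, seed = 7)
  X <- build_design(fx$cohort, covariates = character(0))
  gt <- adjusted_group_test(fx$summaries, X, "global_efficiency", "mean")
  y <- fx$summaries$mean_global_efficiency
  grp <- fx$cohort$records$group
  tt <- t.test(y[grp == "ASD"], y[grp == "TD"], var.equal = TRUE)
  expect_equal(gt$t_value, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(gt$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(gt$direction, sign(mean(y[grp == "ASD"]) - mean(y[grp == "TD"])))
})

test_that("group t-statistic is invariant to affine covariate rescaling", {
  fx <- stats_fixture(shift = 0.02, seed = 11)
  t_raw <- adjusted_group_test(fx$summaries, build_design(fx$cohort),
                               "global_efficiency", "mean")$t_value
  fx$cohort$records$age <- fx$cohort$records$age * 1000 - 300
  fx$cohort$records$iq <- fx$cohort$records$iq / 50 + 2
  t_scaled <- adjusted_group_test(fx$summaries, build_design(fx$cohort),
                                  "global_efficiency", "mean")$t_value
  expect_equal(t_raw, t_scaled, tolerance = 1e-8)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_bh(0.03), 0.03)
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- fdr_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("partial correlation with no covariates is plain Pearson", {
  fx <- stats_fixture(seed = 13)
  pc <- partial_correlation_ados(fx$summaries, fx$cohort, "degree_n01",
                                 "mean", "comm", covariates = character(0))
  rec <- fx$cohort$records
  asd <- rec$group == "ASD"
  r_plain <- cor(fx$summaries$mean_degree_n01[asd], rec$ados_comm[asd])
  expect_equal(pc$r_partial, r_plain, tolerance = 1e-12)
  expect_equal(pc$df, sum(asd) - 2L)
  expect_equal(pc$t_value, r_plain * sqrt(pc$df / (1 - r_plain^2)),
               tolerance = 1e-12)
})

test_that("a generator-coupled symptom score is detected with the right sign", {
  sp <- cohort_spec(n_per_group = c(ASD = 60, TD = 0), t_len = 100,
                    ados_coupling = list(node = 1, coef = -60), seed = 17)
  sim <- simulate_dcc_cohort(sp)
  conn <- vapply(sim$truth$subjects, function(s) mean(s$mean_r[1, -1]), 0)
  # stand-in summary column: the coupled node's realized mean connectivity
  summaries <- data.frame(subject_id = sim$cohort$records$subject_id,
                          mean_degree_n01 = conn)
  pc <- partial_correlation_ados(summaries, sim$cohort, "degree_n01",
                                 "mean", "comm")
  expect_lt(pc$r_partial, -0.2)
  expect_lt(pc$p_value, 0.05)
})

test_that("the full analysis produces the four tables with the fixed schema", {
  fx <- stats_fixture(shift = 0.06, seed = 19)
  res <- run_full_analysis(fx$cohort, fx$summaries)
  for (tab in list(res$group_mean, res$group_variance)) {
    expect_equal(names(tab), c("metric", "summary_kind", "mean_sd_group1",
                               "mean_sd_group2", "t", "p", "p_fdr"))
    expect_equal(nrow(tab), 3L)       # global_efficiency + 2 node degrees
  }
  # node-level family (degree across nodes) gets FDR; network-level does not
  gm <- res$group_mean
  expect_true(all(is.na(gm$p_fdr[gm$metric == "global_efficiency"])))
  deg <- gm[startsWith(gm$metric, "degree_"), ]
  expect_equal(deg$p_fdr, fdr_bh(deg$p))
  # the injected strong shift is detected
  expect_lt(gm$p[gm$metric == "global_efficiency"], 0.01)

  # global FDR family pools everything within a summary kind
  res_g <- run_full_analysis(fx$cohort, fx$summaries, fdr_family = "global")
  expect_equal(res_g$group_mean$p_fdr, fdr_bh(res_g$group_mean$p))

  expect_true(all(c("metric", "summary_kind", "ados_scale", "r", "t", "p",
                    "n_used", "df") %in% names(res$ados_mean)))
  expect_equal(nrow(res$ados_mean), 3L * 4L)
})

test_that("degenerate group sizes yield a missing result with a reason", {
  fx <- stats_fixture(seed = 23)
  keep <- c(which(fx$cohort$records$group == "ASD")[1],
            which(fx$cohort$records$group == "TD"))
  fx$cohort$records <- fx$cohort$records[keep, ]
  X <- build_design(fx$cohort, covariates = character(0))
  gt <- adjusted_group_test(fx$summaries, X, "global_efficiency", "mean")
  expect_true(is.na(gt$t_value))
  expect_match(gt$reason, "fewer than 2")
})
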