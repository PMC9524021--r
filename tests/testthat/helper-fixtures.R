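# small in-code fixtures shared across test files

# a valid 10-record phenotype table: rows 8-10 each violate exactly one
# inclusion criterion (mean FD, percent FD, IQ respectively)
toy_phenotype <- function() {
  data.frame(
    subject_id = sprintf("s%02d", 1:10),
    group = rep(c("ASD", "TD"), 5),
    age = c(12, 14, 16, 18, 20, 22, 24, 26, 28, 30),
    sex = rep(c("M", "F"), 5),
    iq = c(100, 110, 95, 105, 120, 99, 101, 108, 112, 74),   # s10: IQ <= 75
    site = "SITE_A",
    func_mean_fd = c(0.05, 0.08, 0.1, 0.12, 0.15, 0.18, 0.19, 0.25, 0.11, 0.09),  # s08 >= 0.2
    func_perc_fd = c(5, 8, 10, 2, 12, 20, 3, 6, 30, 7),      # s09 >= 25
    ados_total = c(12, NA, 14, NA, 10, NA, 15, NA, 9, NA),
    ados_comm = c(4, NA, 5, NA, 3, NA, 6, NA, 2, NA),
    ados_social = c(8, NA, 9, NA, 7, NA, 9, NA, 7, NA),
    ados_stereo_behav = c(2, NA, 1, NA, 2, NA, 3, NA, 1, NA),
    stringsAsFactors = FALSE)
}

# fake converged garch_fit with prescribed conditional sd path
fake_garch_fit <- function(sigma_t, y = sigma_t) {
  structure(list(coefficients = c(omega = 0.1, alpha = 0.1, beta = 0.8),
                 sigma_t = sigma_t, loglik = 0, converged = TRUE,
                 boundary = FALSE, n = length(sigma_t), y = y),
            class = "garch_fit")
}

# simulate a 2-node DCC pair with known parameters and return the
# standardized-residual pair plus fitted stage-1 models
simulated_pair_fit <- function(theta1, theta2, t_len, seed,
                               rho = 0.5, starts = 3) {
  sp <- cohort_spec(n_per_group = c(ASD = 0, TD = 1), n_nodes = 2,
                    t_len = t_len, theta1 = theta1, theta2 = theta2,
                    qbar_structure = "exchangeable", qbar_offdiag = rho,
                    base_qbar_scale = 1, subject_qbar_sd = 0,
                    group_qbar_scale = 1, group_theta_shift = 0, seed = seed)
  sim <- simulate_dcc_cohort(sp)
  y <- sim$series[[1]]$data
  y <- y - rowMeans(y)
  f1 <- fit_garch(y[1, ], starts = starts)
  f2 <- fit_garch(y[2, ], starts = starts)
  eps <- standardized_residuals(y, f1, f2)
  fit_dcc_pair(eps, starts = starts)
}

# write a small time-series file for a parcellation; returns the path
write_ts_fixture <- function(dir, parc, t_len = 150, seed = 1,
                             permute = FALSE, drop = NULL, name = "subA.tsv") {
  set.seed(seed)
  n <- attr(parc, "n")
  tab <- as.data.frame(matrix(rnorm(t_len * n), t_len, n))
  names(tab) <- parc$abbrev
  if (permute) tab <- tab[, sample(names(tab))]
  if (!is.null(drop)) tab[[drop]] <- NULL
  path <- file.path(dir, name)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
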