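# synthetic DCC-GARCH cohort generator: known ground truth for every
# downstream stage

#' Simulate a univariate GARCH(1,1) series
#'
#' Draws `y_t = sigma_t * z_t` with Gaussian innovations and conditional
#' variance `sigma^2_t = omega + alpha * y^2_{t-1} + beta * sigma^2_{t-1}`.
#' The recursion starts at the unconditional variance
#' `omega / (1 - alpha - beta)`, so the process is stationary from the first
#' sample and its expected variance equals that value.
#'
#' @param omega positive baseline variance parameter.
#' @param alpha,beta non-negative ARCH and GARCH loads with `alpha + beta < 1`.
#' @param t_len series length.
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of length `t_len`.
#' @export
simulate_garch_series <- function(omega, alpha, beta, t_len, seed = NULL) {
  check_garch_params(omega, alpha, beta)
  if (t_len < 1L) stopf("t_len must be positive")
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(t_len)
  y <- numeric(t_len)
  s2 <- omega / (1 - alpha - beta)
  y[1L] <- sqrt(s2) * z[1L]
  if (t_len > 1L) {
    for (t in 2:t_len) {
      s2 <- omega + alpha * y[t - 1L]^2 + beta * s2
      y[t] <- sqrt(s2) * z[t]
    }
  }
  y
}

check_garch_params <- function(omega, alpha, beta) {
  if (omega <= 0) stopf("omega must be > 0")
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be >= 0")
  if (alpha + beta >= 1) stopf("alpha + beta must be < 1 (got %g)", alpha + beta)
  invisible(TRUE)
}

#' Specify a synthetic two-group cohort
#'
#' Collects every knob of the generator: network size, series length, the
#' GARCH(1,1) parameters shared by all nodes, the DCC loadings `theta1`,
#' `theta2`, the long-run correlation level, group effects (patient-like group
#' = scaled-down long-run correlations, inflated `theta1`), between-subject
#' variability, covariate distributions, sites, and an optional coupling that
#' ties generated ADOS symptom scores to a node's mean connectivity.
#'
#' @param n_per_group integer vector `c(ASD = ..., TD = ...)`.
#' @param n_nodes number of network nodes.
#' @param t_len returned series length (after the internal burn-in).
#' @param tr sampling interval in seconds.
#' @param garch list with `omega`, `alpha`, `beta` for every node.
#' @param theta1,theta2 DCC recursion loadings, `theta1 + theta2 < 1`.
#' @param qbar_structure `"hub"` (default) gives node 1 strong long-run
#'   correlations `hub_strength` to every other node and `qbar_offdiag`
#'   elsewhere, mimicking the core-hub organization of resting-state
#'   networks; `"exchangeable"` uses `qbar_offdiag` everywhere.
#' @param hub_strength long-run correlation between the hub node and the
#'   rest under the `"hub"` structure.
#' @param qbar_offdiag long-run correlation between non-hub node pairs.
#' @param qbar optional explicit long-run correlation matrix (overrides the
#'   structural options).
#' @param base_qbar_scale scale applied to every subject's long-run
#'   off-diagonals before group effects, leaving headroom for
#'   between-subject jitter (default 0.9).
#' @param group_qbar_scale multiplier in (0, 1] on the patient group's
#'   long-run off-diagonals (lower mean connectivity; default 0.5).
#' @param group_theta_shift additive shift on the patient group's `theta1`
#'   (more volatile connectivity; default 0.05).
#' @param subject_qbar_sd sd of the log-normal between-subject jitter on the
#'   long-run scale (default 0.1).
#' @param ados_coupling list `list(node =, coef =)` linking a subject's
#'   time-averaged connectivity of that node to their ADOS scores; `coef = 0`
#'   or `node = NULL` disables the coupling.
#' @param sites character vector of site labels cycled over subjects.
#' @param age_mean,age_sd,iq_mean,iq_sd,fd_mean,fd_sd covariate distributions.
#' @param innovations `"gaussian"` (default) or `"student"` for heavy-tailed
#'   innovations (df 5) in robustness experiments.
#' @param seed master integer seed; every subject's seed is derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(ASD = 10, TD = 10),
                        n_nodes = 6, t_len = 300, tr = 2,
                        garch = list(omega = 0.1, alpha = 0.1, beta = 0.8),
                        theta1 = 0.05, theta2 = 0.85,
                        qbar_structure = c("hub", "exchangeable"),
                        hub_strength = 0.6, qbar_offdiag = 0.25, qbar = NULL,
                        base_qbar_scale = 0.9,
                        group_qbar_scale = 0.5, group_theta_shift = 0.05,
                        subject_qbar_sd = 0.1,
                        ados_coupling = list(node = NULL, coef = 0),
                        sites = c("SITE_A", "SITE_B"),
                        age_mean = 16, age_sd = 6,
                        iq_mean = 108, iq_sd = 13,
                        fd_mean = 0.09, fd_sd = 0.04,
                        innovations = c("gaussian", "student"),
                        seed = 1L) {
  innovations <- match.arg(innovations)
  qbar_structure <- match.arg(qbar_structure)
  if (is.null(names(n_per_group))) names(n_per_group) <- c("ASD", "TD")
  check_garch_params(garch$omega, garch$alpha, garch$beta)
  if (theta1 < 0 || theta2 < 0 || theta1 + theta2 >= 1) {
    stopf("need theta1, theta2 >= 0 and theta1 + theta2 < 1")
  }
  if (theta1 + group_theta_shift + theta2 >= 1) {
    stopf("group_theta_shift %g makes patient theta1 + theta2 >= 1", group_theta_shift)
  }
  if (group_qbar_scale <= 0 || group_qbar_scale > 1) {
    stopf("group_qbar_scale must be in (0, 1]")
  }
  if (is.null(qbar)) {
    qbar <- matrix(qbar_offdiag, n_nodes, n_nodes)
    if (qbar_structure == "hub") {
      qbar[1L, ] <- qbar[, 1L] <- hub_strength
    }
    diag(qbar) <- 1
  }
  stopifnot(nrow(qbar) == n_nodes, ncol(qbar) == n_nodes)
  ev <- eigen(qbar, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("qbar must be positive definite")
  structure(list(n_per_group = n_per_group, n_nodes = n_nodes, t_len = t_len,
                 tr = tr, garch = garch, theta1 = theta1, theta2 = theta2,
                 qbar = qbar, base_qbar_scale = base_qbar_scale,
                 group_qbar_scale = group_qbar_scale,
                 group_theta_shift = group_theta_shift,
                 subject_qbar_sd = subject_qbar_sd,
                 ados_coupling = ados_coupling, sites = sites,
                 age_mean = age_mean, age_sd = age_sd,
                 iq_mean = iq_mean, iq_sd = iq_sd,
                 fd_mean = fd_mean, fd_sd = fd_sd,
                 innovations = innovations, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort spec: %s subjects, %d nodes, T = %d\n",
                     "  theta = (%g, %g), qbar scale: patient x%g, theta1 shift +%g\n"),
              paste(sprintf("%d %s", x$n_per_group, names(x$n_per_group)),
                    collapse = " + "),
              x$n_nodes, x$t_len, x$theta1, x$theta2,
              x$group_qbar_scale, x$group_theta_shift))
  invisible(x)
}

# one subject's N-dimensional DCC-GARCH draw; returns the series, the true
# R_t tensor, and realized summaries. Burn-in samples are discarded.
simulate_dcc_subject <- function(n_nodes, t_len, garch, theta1, theta2, qbar,
                                 burn = 200L, innovations = "gaussian",
                                 keep_rt = FALSE) {
  omega <- rep_len(garch$omega, n_nodes)
  alpha <- rep_len(garch$alpha, n_nodes)
  beta  <- rep_len(garch$beta, n_nodes)
  t_tot <- t_len + burn
  y <- matrix(0, n_nodes, t_tot)
  rt <- if (keep_rt) array(NA_real_, c(n_nodes, n_nodes, t_len)) else NULL
  conn_sum <- matrix(0, n_nodes, n_nodes)
  Q <- qbar
  eps_prev <- numeric(n_nodes)
  s2 <- omega / (1 - alpha - beta)
  y2_prev <- numeric(n_nodes)
  for (t in seq_len(t_tot)) {
    if (t > 1L) {
      Q <- (1 - theta1 - theta2) * qbar +
        theta1 * tcrossprod(eps_prev) + theta2 * Q
      s2 <- omega + alpha * y2_prev + beta * s2
    }
    d <- sqrt(diag(Q))
    R <- Q / tcrossprod(d)
    diag(R) <- 1
    z <- if (innovations == "student") {
      df <- 5
      stats::rt(n_nodes, df = df) / sqrt(df / (df - 2))
    } else stats::rnorm(n_nodes)
    eps <- drop(crossprod(chol(R), z))
    y[, t] <- sqrt(s2) * eps
    y2_prev <- y[, t]^2
    eps_prev <- eps
    if (t > burn) {
      k <- t - burn
      if (keep_rt) rt[, , k] <- R
      conn_sum <- conn_sum + R
    }
  }
  list(y = y[, (burn + 1L):t_tot, drop = FALSE],
       rt = rt, mean_r = conn_sum / t_len)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a two-group cohort of DCC-GARCH time series
#'
#' Draws, for every subject, an `n_nodes`-dimensional zero-mean series whose
#' conditional variances follow GARCH(1,1) and whose time-varying correlation
#' matrix follows the DCC recursion around a subject-specific long-run
#' correlation matrix. The patient-like (ASD-labelled) group receives
#' off-diagonals scaled by `group_qbar_scale` (lower mean connectivity) and
#' `theta1` shifted up by `group_theta_shift` (more volatile connectivity).
#' Phenotype covariates, sites and (for the patient group) ADOS symptom
#' scores are generated alongside; with a non-zero `ados_coupling` the scores
#' are a linear function of the subject's realized time-averaged connectivity
#' of the coupled node plus Gaussian noise, truncated to non-negative
#' integers. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @param keep_rt keep each subject's true correlation tensor in the ground
#'   truth (memory-heavy; default FALSE).
#' @return A list with elements `cohort` (a [cohort]), `series` (named list of
#'   [subject_ts]), and `truth` (per-subject generator parameters, realized
#'   mean connectivity, and — optionally — the true `R_t` tensor).
#' @export
simulate_dcc_cohort <- function(spec, keep_rt = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n_sub <- length(groups)
  ids <- sprintf("sub%03d", seq_len(n_sub))
  site <- rep_len(spec$sites, n_sub)
  labels <- sprintf("n%02d", seq_len(spec$n_nodes))

  series <- vector("list", n_sub)
  names(series) <- ids
  truth <- vector("list", n_sub)
  rec <- vector("list", n_sub)

  for (i in seq_len(n_sub)) {
    set.seed(derive_seed(spec$seed, i))
    patient <- groups[i] == "ASD"
    g_scale <- if (patient) spec$group_qbar_scale else 1
    th1 <- spec$theta1 + if (patient) spec$group_theta_shift else 0
    s_subj <- clip(spec$base_qbar_scale * g_scale *
                     exp(stats::rnorm(1, 0, spec$subject_qbar_sd)), 0.05, 1)
    qb <- spec$qbar * s_subj
    diag(qb) <- 1
    sim <- simulate_dcc_subject(spec$n_nodes, spec$t_len, spec$garch,
                                th1, spec$theta2, qb,
                                innovations = spec$innovations,
                                keep_rt = keep_rt)
    rownames(sim$y) <- labels
    series[[i]] <- subject_ts(sim$y, subject_id = ids[i], tr = spec$tr)

    age <- clip(stats::rnorm(1, spec$age_mean, spec$age_sd), 6, 45)
    iq <- round(clip(stats::rnorm(1, spec$iq_mean, spec$iq_sd), 76, 150))
    fd <- clip(stats::rnorm(1, spec$fd_mean, spec$fd_sd), 0.01, 0.19)
    pfd <- clip(stats::rnorm(1, 8, 5), 0, 24)
    sex <- if (stats::runif(1) < 0.85) "M" else "F"

    ados <- rep(NA_real_, 4)
    if (patient) {
      cp <- spec$ados_coupling
      conn <- if (!is.null(cp$node) && cp$coef != 0) {
        mean(sim$mean_r[cp$node, -cp$node])
      } else 0
      slope <- if (!is.null(cp$node)) cp$coef else 0
      comm <- max(0, round(4 + slope * conn + stats::rnorm(1, 0, 1.5)))
      social <- max(0, round(8 + slope * conn + stats::rnorm(1, 0, 2)))
      stereo <- max(0, round(2 + stats::rnorm(1, 0, 1)))
      ados <- c(comm + social, comm, social, stereo)
    }
    rec[[i]] <- data.frame(subject_id = ids[i], group = groups[i], age = age,
                           sex = sex, iq = iq, site = site[i],
                           func_mean_fd = fd, func_perc_fd = pfd,
                           ados_total = ados[1], ados_comm = ados[2],
                           ados_social = ados[3], ados_stereo_behav = ados[4],
                           stringsAsFactors = FALSE)
    truth[[i]] <- list(subject_id = ids[i], group = groups[i],
                       theta1 = th1, theta2 = spec$theta2,
                       qbar_scale = s_subj, garch = spec$garch,
                       mean_r = sim$mean_r, rt = sim$rt)
  }
  names(truth) <- ids
  list(cohort = cohort(do.call(rbind, rec)), series = series,
       truth = structure(list(spec = spec, subjects = truth),
                         class = "cohort_truth"))
}

#' Write a simulated cohort to disk
#'
#' Writes the phenotype CSV, one TSV per subject time series, and a
#' ground-truth JSON holding the full generator specification and every
#' subject's parameters.
#'
#' @param sim result of [simulate_dcc_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  write_phenotype(sim$cohort, file.path(dir, "phenotype.csv"))
  for (id in names(sim$series)) {
    write_timeseries(sim$series[[id]], file.path(dir, "series", paste0(id, ".tsv")))
  }
  tr <- lapply(sim$truth$subjects, function(s) {
    s$mean_r <- NULL; s$rt <- NULL; s
  })
  spec <- sim$truth$spec
  spec$qbar <- as.vector(spec$qbar)
  jsonlite::write_json(list(spec = unclass(spec), subjects = tr),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
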