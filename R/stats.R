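# inferential layer: covariate-adjusted group contrasts with BH-FDR over
# node-level parameters, and covariate-adjusted symptom correlations

DEFAULT_COVARIATES <- c("age", "func_mean_fd", "func_perc_fd", "iq", "sex", "site")

#' Build the covariate design matrix of a cohort
#'
#' Columns: intercept, optionally a group indicator (ASD = 1, TD = 0), the
#' continuous covariates age, IQ and the two motion summaries, a sex
#' indicator, and reference-coded site indicators (largest site as
#' reference). Subjects missing any required covariate are dropped and
#' listed in the `"dropped"` attribute. A single-site cohort gets no site
#' columns (with a warning); rank deficiency is an error naming the
#' collinear columns.
#'
#' @param x a [cohort].
#' @param include_group add the ASD-vs-TD indicator column (default TRUE).
#' @param covariates covariate names to control for (default: age, motion
#'   summaries, IQ, sex, site).
#' @return A `design_matrix` object: the numeric matrix with attributes
#'   `subject_id`, `group_col`, `covariate_cols`, `dropped`.
#' @export
build_design <- function(x, include_group = TRUE,
                         covariates = DEFAULT_COVARIATES) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  needed <- intersect(c(covariates, if (include_group) "group"), names(rec))
  complete <- stats::complete.cases(rec[, needed, drop = FALSE])
  dropped <- rec$subject_id[!complete]
  if (length(dropped)) {
    dccmst_log("build_design: dropping subjects with missing covariates: ",
               paste(dropped, collapse = ", "))
  }
  rec <- rec[complete, , drop = FALSE]
  if (!nrow(rec)) stopf("no subjects with complete covariates")

  cols <- list("(Intercept)" = rep(1, nrow(rec)))
  if (include_group) cols$group_ASD <- as.numeric(rec$group == "ASD")
  for (cv in covariates) {
    if (cv == "sex") {
      sx <- factor(rec$sex)
      ref <- names(sort(table(sx), decreasing = TRUE))[1L]
      for (lv in setdiff(levels(sx), ref)) {
        cols[[paste0("sex_", lv)]] <- as.numeric(sx == lv)
      }
    } else if (cv == "site") {
      st <- factor(rec$site)
      if (nlevels(st) < 2L) {
        warnf("single-site cohort: site columns omitted from the design")
        next
      }
      ref <- names(sort(table(st), decreasing = TRUE))[1L]
      for (lv in setdiff(levels(st), ref)) {
        cols[[paste0("site_", lv)]] <- as.numeric(st == lv)
      }
    } else {
      cols[[cv]] <- as.numeric(rec[[cv]])
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  structure(X, class = c("design_matrix", "matrix", "array"),
            subject_id = rec$subject_id,
            group_col = if (include_group) "group_ASD" else NULL,
            covariate_cols = setdiff(colnames(X), c("(Intercept)", "group_ASD")),
            dropped = dropped)
}

align_summary <- function(summaries, design, metric, summary_kind) {
  col <- paste0(switch(summary_kind, mean = "mean_", variance = "var_"), metric)
  if (!col %in% names(summaries)) stopf("summary column '%s' not found", col)
  ids <- attr(design, "subject_id")
  pos <- match(ids, summaries$subject_id)
  keep <- !is.na(pos) & !is.na(summaries[[col]][pos])
  list(y = summaries[[col]][pos[keep]], keep = keep, col = col)
}

#' Covariate-adjusted group comparison of one summary statistic
#'
#' Fits the linear model `summary ~ group + covariates` and reports the
#' two-sided t-test of the group coefficient — the conventional estimator of
#' a group contrast "after controlling" confounds. With no covariates and
#' balanced groups this reduces exactly to the pooled two-sample t-test.
#'
#' @param summaries wide cohort summary table from [cohort_summaries()].
#' @param design a [build_design()] result containing the group column.
#' @param metric metric name (e.g. `"global_efficiency"`, `"degree_n01"`).
#' @param summary_kind `"mean"` or `"variance"`.
#' @return A `group_test` list: `metric`, `summary_kind`, `t_value`,
#'   `p_value`, `direction` (sign of the adjusted ASD - TD difference),
#'   `estimate`, `n_used`, `df`.
#' @export
adjusted_group_test <- function(summaries, design, metric,
                                summary_kind = c("mean", "variance")) {
  summary_kind <- match.arg(summary_kind)
  if (is.null(attr(design, "group_col"))) {
    stopf("design was built without a group column")
  }
  al <- align_summary(summaries, design, metric, summary_kind)
  X <- unclass(design)[al$keep, , drop = FALSE]
  y <- al$y
  grp <- X[, "group_ASD"]
  if (length(unique(grp[!is.na(y)])) < 2L || min(table(grp)) < 2L) {
    return(structure(list(metric = metric, summary_kind = summary_kind,
                          t_value = NA_real_, p_value = NA_real_,
                          direction = NA_real_, estimate = NA_real_,
                          n_used = length(y), df = NA_integer_,
                          reason = "fewer than 2 subjects in a group"),
                     class = "group_test"))
  }
  fit <- stats::lm.fit(X, y)
  df <- length(y) - fit$rank
  if (df < 1L || stats::var(fit$residuals) < 1e-30) {
    return(structure(list(metric = metric, summary_kind = summary_kind,
                          t_value = NA_real_, p_value = NA_real_,
                          direction = NA_real_, estimate = NA_real_,
                          n_used = length(y), df = df,
                          reason = "degenerate residual variance"),
                     class = "group_test"))
  }
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(qr.R(fit$qr))
  g <- match("group_ASD", colnames(X))
  se <- sqrt(sigma2 * XtX_inv[g, g])
  est <- unname(fit$coefficients[g])
  tval <- est / se
  structure(list(metric = metric, summary_kind = summary_kind,
                 t_value = tval,
                 p_value = 2 * stats::pt(-abs(tval), df),
                 direction = sign(est), estimate = est,
                 n_used = length(y), df = df, reason = NULL),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Adjusted group test: %s (%s)\n  t = %.3f, p = %.4g (n = %d, df = %d)\n",
              x$metric, x$summary_kind, x$t_value, x$p_value, x$n_used, x$df))
  if (!is.null(x$reason)) cat("  not computed:", x$reason, "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1] (NAs pass through).
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted Pearson correlation with an ADOS scale
#'
#' Residualizes both the chosen summary statistic and the ADOS score on the
#' covariate columns of a group-free design (ASD subjects only), takes the
#' Pearson correlation of the residuals, and assesses it with the t-statistic
#' `t = r * sqrt(df / (1 - r^2))`, `df = n - 2 - k` where `k` is the number
#' of controlled covariate columns.
#'
#' @param summaries wide cohort summary table.
#' @param cohort_x the [cohort] providing ADOS scores and covariates.
#' @param metric metric name.
#' @param summary_kind `"mean"` or `"variance"`.
#' @param ados_scale one of `"total"`, `"comm"`, `"social"`, `"stereo_behav"`.
#' @param covariates covariates to control (default as in [build_design()]).
#' @return An `ados_correlation` list: `r_partial`, `t_value`, `p_value`,
#'   `n_used`, `df`, plus identifiers.
#' @export
partial_correlation_ados <- function(summaries, cohort_x, metric,
                                     summary_kind = c("mean", "variance"),
                                     ados_scale = c("total", "comm", "social",
                                                    "stereo_behav"),
                                     covariates = DEFAULT_COVARIATES) {
  summary_kind <- match.arg(summary_kind)
  ados_scale <- match.arg(ados_scale)
  stopifnot(inherits(cohort_x, "cohort"))
  ados_col <- paste0("ados_", ados_scale)

  rec <- cohort_x$records
  asd <- cohort_x
  asd$records <- rec[rec$group == "ASD" & !is.na(rec[[ados_col]]), , drop = FALSE]
  if (!nrow(asd$records)) {
    stopf("no ASD subjects with a valid %s score", ados_col)
  }
  design <- build_design(asd, include_group = FALSE, covariates = covariates)
  al <- align_summary(summaries, design, metric, summary_kind)
  X <- unclass(design)[al$keep, , drop = FALSE]
  y <- al$y
  ids <- attr(design, "subject_id")[al$keep]
  ados <- asd$records[[ados_col]][match(ids, asd$records$subject_id)]
  k <- length(attr(design, "covariate_cols"))
  n <- length(y)
  if (n < k + 4L) {
    return(structure(list(metric = metric, summary_kind = summary_kind,
                          ados_scale = toupper(ados_scale),
                          r_partial = NA_real_, t_value = NA_real_,
                          p_value = NA_real_, n_used = n, df = NA_integer_,
                          reason = sprintf("n = %d too small for %d covariates", n, k)),
                     class = "ados_correlation"))
  }
  res_y <- stats::lm.fit(X, y)$residuals
  res_a <- stats::lm.fit(X, ados)$residuals
  if (stats::sd(res_y) < 1e-30 || stats::sd(res_a) < 1e-30) {
    return(structure(list(metric = metric, summary_kind = summary_kind,
                          ados_scale = toupper(ados_scale),
                          r_partial = NA_real_, t_value = NA_real_,
                          p_value = NA_real_, n_used = n, df = NA_integer_,
                          reason = "degenerate residual variance"),
                     class = "ados_correlation"))
  }
  r <- stats::cor(res_y, res_a)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(metric = metric, summary_kind = summary_kind,
                 ados_scale = toupper(ados_scale), r_partial = r,
                 t_value = tval, p_value = 2 * stats::pt(-abs(tval), df),
                 n_used = n, df = df, reason = NULL),
            class = "ados_correlation")
}

#' @export
print.ados_correlation <- function(x, ...) {
  cat(sprintf("Partial correlation: %s (%s) vs ADOS_%s\n  r = %.4f, t = %.3f, p = %.4g (n = %d, df = %d)\n",
              x$metric, x$summary_kind, x$ados_scale, x$r_partial, x$t_value,
              x$p_value, x$n_used, x$df))
  invisible(x)
}

metric_family <- function(metric) {
  m <- regmatches(metric, regexpr("^(degree|betweenness|eccentricity)(?=_)",
                                  metric, perl = TRUE))
  if (length(m)) m else "network"
}

format_mean_sd <- function(m, s) sprintf("%.4g ± %.4g", m, s)

#' Run the complete inferential analysis of a summarized cohort
#'
#' Produces four result tables: covariate-adjusted ASD-vs-TD contrasts on the
#' temporal means and on the temporal variances of every tree parameter, and
#' covariate-adjusted Pearson correlations of both summary statistics with
#' the four ADOS severity scales (ASD subjects only, all metrics — not just
#' the group-significant ones). FDR adjustment is applied within each family
#' of one node-level parameter type and one summary kind across nodes;
#' network-level parameters are unadjusted unless `fdr_family = "global"`,
#' which pools every parameter of a summary kind into one family.
#'
#' @param cohort_x a [cohort].
#' @param summaries wide table from [cohort_summaries()].
#' @param covariates covariates to control.
#' @param fdr_family `"node"` (default) or `"global"`.
#' @param alpha significance threshold recorded in the audit (default 0.05).
#' @return An `mst_analysis` list: `group_mean`, `group_variance` (columns
#'   `metric`, `summary_kind`, `mean_sd_group1`, `mean_sd_group2`, `t`, `p`,
#'   `p_fdr`), `ados_mean`, `ados_variance`, and `audit` (exclusions,
#'   families, coding, alpha).
#' @export
run_full_analysis <- function(cohort_x, summaries,
                              covariates = DEFAULT_COVARIATES,
                              fdr_family = c("node", "global"),
                              alpha = 0.05) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(cohort_x, "cohort"))
  design <- build_design(cohort_x, include_group = TRUE, covariates = covariates)
  metrics <- sub("^mean_", "", grep("^mean_", names(summaries), value = TRUE))
  rec <- cohort_x$records

  group_table <- function(kind) {
    prefix <- if (kind == "mean") "mean_" else "var_"
    rows <- lapply(metrics, function(m) {
      gt <- adjusted_group_test(summaries, design, m, kind)
      col <- paste0(prefix, m)
      v_asd <- summaries[[col]][summaries$subject_id %in%
                                  rec$subject_id[rec$group == "ASD"]]
      v_td <- summaries[[col]][summaries$subject_id %in%
                                 rec$subject_id[rec$group == "TD"]]
      data.frame(metric = m, summary_kind = kind,
                 mean_sd_group1 = format_mean_sd(mean(v_asd, na.rm = TRUE),
                                                 stats::sd(v_asd, na.rm = TRUE)),
                 mean_sd_group2 = format_mean_sd(mean(v_td, na.rm = TRUE),
                                                 stats::sd(v_td, na.rm = TRUE)),
                 t = gt$t_value, p = gt$p_value, p_fdr = NA_real_,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    fam <- vapply(tab$metric, metric_family, "")
    if (fdr_family == "global") {
      tab$p_fdr <- fdr_bh(tab$p)
    } else {
      for (f in setdiff(unique(fam), "network")) {
        idx <- fam == f
        tab$p_fdr[idx] <- fdr_bh(tab$p[idx])
      }
    }
    tab
  }

  ados_table <- function(kind) {
    scales <- c("total", "comm", "social", "stereo_behav")
    rows <- lapply(metrics, function(m) {
      do.call(rbind, lapply(scales, function(sc) {
        ac <- tryCatch(
          partial_correlation_ados(summaries, cohort_x, m, kind, sc, covariates),
          error = function(e) {
            list(r_partial = NA_real_, t_value = NA_real_, p_value = NA_real_,
                 n_used = NA_integer_, df = NA_integer_,
                 reason = conditionMessage(e))
          })
        data.frame(metric = m, summary_kind = kind,
                   ados_scale = toupper(sc), r = ac$r_partial, t = ac$t_value,
                   p = ac$p_value, n_used = ac$n_used, df = ac$df,
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  }

  structure(list(group_mean = group_table("mean"),
                 group_variance = group_table("variance"),
                 ados_mean = ados_table("mean"),
                 ados_variance = ados_table("variance"),
                 audit = list(alpha = alpha, fdr_family = fdr_family,
                              covariates = covariates,
                              design_columns = colnames(design),
                              dropped_subjects = attr(design, "dropped"),
                              n_design = nrow(design))),
            class = "mst_analysis")
}

#' @export
print.mst_analysis <- function(x, ...) {
  sig_m <- x$group_mean[!is.na(x$group_mean$p) & x$group_mean$p < x$audit$alpha, ]
  sig_v <- x$group_variance[!is.na(x$group_variance$p) &
                              x$group_variance$p < x$audit$alpha, ]
  cat(sprintf("MST cohort analysis (%d subjects in design, alpha = %g)\n",
              x$audit$n_design, x$audit$alpha))
  cat(sprintf("  group differences: %d on temporal means, %d on temporal variances (unadjusted p)\n",
              nrow(sig_m), nrow(sig_v)))
  cat(sprintf("  ADOS correlation rows: %d (means) + %d (variances)\n",
              NROW(x$ados_mean), NROW(x$ados_variance)))
  invisible(x)
}
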