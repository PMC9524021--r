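# stage 2 of the DCC estimator: per-pair correlation dynamics, and the
# subject-level N x N x T connectivity tensor

dcc_rt <- function(theta1, theta2, qb, p11, p12, p22) {
  .dcc_rt_c(theta1, theta2, qb, p11, p12, p22)
}

dcc_nll_r <- function(r, p11, p12, p22) {
  r2 <- pmin(r * r, 1 - 1e-12)
  0.5 * sum(log1p(-r2) + (p11 + p22 - 2 * r * p12) / (1 - r2) - p11 - p22)
}

#' Fit the bivariate DCC correlation recursion to standardized residuals
#'
#' Given stage-1 standardized residuals `eps` (2 x T), computes the long-run
#' matrix `Qbar = (1/T) * sum_t eps_t eps_t'` and estimates the loadings
#' `(theta1, theta2)` of the recursion
#' `Q_t = (1 - theta1 - theta2) Qbar + theta1 eps_{t-1} eps_{t-1}' + theta2 Q_{t-1}`
#' by maximizing the second-stage Gaussian quasi-likelihood under
#' `theta1, theta2 >= 0`, `theta1 + theta2 < 1`. The recursion is initialized
#' at `Qbar`; the dynamic correlation is the rescaling
#' `r_t = q12_t / sqrt(q11_t q22_t)`, which lies in [-1, 1] by construction
#' (each `Q_t` is a nonnegative combination of positive semi-definite
#' matrices).
#'
#' @param eps 2 x T matrix of standardized residuals, T >= 50.
#' @param theta optional fixed `c(theta1, theta2)`; when supplied the
#'   optimization is skipped (e.g. `c(0, 0)` gives the constant rescaled
#'   `Qbar` correlation).
#' @param starts number of optimizer starting points (default 3).
#' @param control passed to [stats::optim()].
#' @return An object of class `dcc_fit` with `theta`, `qbar` (2 x 2), `r_t`
#'   (length T), `eps`, `loglik` (correlation-stage quasi-log-likelihood),
#'   `converged` and `boundary` flags.
#' @examples
#' e <- matrix(rnorm(400), 2, 200)
#' fit <- fit_dcc_pair(e, theta = c(0, 0))
#' range(fit$r_t)
#' @export
fit_dcc_pair <- function(eps, theta = NULL, starts = 3,
                         control = list(reltol = 1e-8)) {
  stopifnot(is.matrix(eps), nrow(eps) == 2L)
  n <- ncol(eps)
  if (is.null(theta) && n < 50L) {
    stopf("fit_dcc_pair needs at least 50 time points (got %d)", n)
  }
  if (anyNA(eps) || any(!is.finite(eps))) stopf("residuals must be finite")
  e1 <- eps[1L, ]; e2 <- eps[2L, ]
  p11 <- e1 * e1; p12 <- e1 * e2; p22 <- e2 * e2
  qbar <- tcrossprod(eps) / n
  qb <- c(qbar[1L, 1L], qbar[1L, 2L], qbar[2L, 2L])

  if (!is.null(theta)) {
    stopifnot(length(theta) == 2L, all(theta >= 0), sum(theta) < 1)
    r_t <- dcc_rt(theta[1L], theta[2L], qb, p11, p12, p22)
    return(structure(list(theta = c(theta1 = theta[1L], theta2 = theta[2L]),
                          qbar = qbar, r_t = r_t, eps = eps,
                          loglik = -dcc_nll_r(r_t, p11, p12, p22),
                          converged = TRUE, boundary = FALSE, fixed = TRUE,
                          n = n), class = "dcc_fit"))
  }

  nll <- function(par) {
    th <- to_simplex(par)
    .dcc_nll_c(th[1L], th[2L], qb, p11, p12, p22)
  }
  start_th <- list(c(0.05, 0.90), c(0.02, 0.80), c(0.10, 0.60))
  start_th <- start_th[seq_len(min(starts, length(start_th)))]
  cand <- list()
  for (th in start_th) {
    opt <- try(stats::optim(from_simplex(th), nll, method = "Nelder-Mead",
                            control = control), silent = TRUE)
    if (!inherits(opt, "try-error")) cand <- c(cand, list(opt))
  }
  best <- if (length(cand)) pick_interior(cand) else NULL
  if (is.null(best)) {
    # degenerate fallback: constant rescaled long-run correlation
    warnf("DCC optimization failed; falling back to the constant rescaled Qbar correlation")
    fb <- fit_dcc_pair(eps, theta = c(0, 0))
    fb$converged <- FALSE
    return(fb)
  }
  th <- to_simplex(best$par)
  r_t <- dcc_rt(th[1L], th[2L], qb, p11, p12, p22)
  structure(list(theta = c(theta1 = th[1L], theta2 = th[2L]), qbar = qbar,
                 r_t = r_t, eps = eps,
                 loglik = -best$value,
                 converged = best$convergence == 0 && all(is.finite(r_t)),
                 boundary = sum(th) >= 1 - 1e-4, fixed = FALSE, n = n),
            class = "dcc_fit")
}

#' @export
print.dcc_fit <- function(x, digits = 4, ...) {
  cat("Bivariate DCC fit (correlation stage)\n")
  print(round(x$theta, digits))
  cat(sprintf("long-run correlation %.4f; r_t in [%.4f, %.4f]; logLik %.3f%s%s\n",
              x$qbar[1L, 2L] / sqrt(x$qbar[1L, 1L] * x$qbar[2L, 2L]),
              min(x$r_t), max(x$r_t), x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$boundary) " [boundary: theta1 + theta2 ~ 1]" else ""))
  invisible(x)
}

#' @export
coef.dcc_fit <- function(object, ...) object$theta

#' @export
logLik.dcc_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
plot.dcc_fit <- function(x, ...) {
  graphics::plot(x$r_t, type = "l", ylim = c(-1, 1), xlab = "time point",
                 ylab = expression(r[t]), main = "Dynamic correlation", ...)
  graphics::abline(h = x$qbar[1L, 2L] / sqrt(x$qbar[1L, 1L] * x$qbar[2L, 2L]),
                   lty = 2, col = "grey50")
  invisible(x)
}

#' Estimate the full time-varying connectivity tensor of a subject
#'
#' Runs the two-stage DCC-GARCH estimator over every node and node pair of a
#' subject: one GARCH(1,1) fit per ROI series (rows are demeaned first if
#' needed), then one bivariate correlation-stage fit per unordered ROI pair.
#' The result is the N x N x T tensor `C[i, j, t]`, symmetric in its first
#' two indices with unit diagonal. Convergence information for every series
#' and pair is retained in the fit report; a pair whose correlation stage
#' fails falls back to its constant rescaled long-run correlation and is
#' flagged.
#'
#' @param ts a [subject_ts].
#' @param starts optimizer starts for both stages (default 3).
#' @return An object of class `dcc_connectivity`: list with `tensor`
#'   (N x N x T, dimnames from the ROI labels), `subject_id`, and `report`
#'   (data frames `series` and `pairs`).
#' @export
connectivity_tensor <- function(ts, starts = 3) {
  stopifnot(inherits(ts, "subject_ts"))
  y <- ts$data
  if (!ts$demeaned) y <- y - rowMeans(y)
  n <- nrow(y); t_len <- ncol(y)
  labels <- rownames(y) %||% sprintf("n%02d", seq_len(n))

  fits <- vector("list", n)
  for (i in seq_len(n)) {
    fits[[i]] <- tryCatch(fit_garch(y[i, ], starts = starts),
                          error = function(e) {
                            stopf("subject %s: GARCH stage failed for ROI %s: %s",
                                  ts$subject_id, labels[i], conditionMessage(e))
                          })
  }
  eps <- do.call(rbind, lapply(fits, residuals))

  tensor <- array(NA_real_, c(n, n, t_len), dimnames = list(labels, labels, NULL))
  for (t in seq_len(t_len)) tensor[, , t][cbind(seq_len(n), seq_len(n))] <- 1

  pair_idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pair_rep <- vector("list", nrow(pair_idx))
  for (k in seq_len(nrow(pair_idx))) {
    i <- pair_idx[k, 1L]; j <- pair_idx[k, 2L]
    pf <- fit_dcc_pair(eps[c(i, j), , drop = FALSE], starts = starts)
    tensor[i, j, ] <- pf$r_t
    tensor[j, i, ] <- pf$r_t
    pair_rep[[k]] <- data.frame(roi_i = labels[i], roi_j = labels[j],
                                theta1 = pf$theta[1L], theta2 = pf$theta[2L],
                                loglik = pf$loglik, converged = pf$converged,
                                boundary = pf$boundary,
                                stringsAsFactors = FALSE)
  }
  series_rep <- data.frame(
    roi = labels,
    omega = vapply(fits, function(f) f$coefficients[1L], 0),
    alpha = vapply(fits, function(f) f$coefficients[2L], 0),
    beta = vapply(fits, function(f) f$coefficients[3L], 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    converged = vapply(fits, function(f) f$converged, NA),
    stringsAsFactors = FALSE)
  structure(list(tensor = tensor, subject_id = ts$subject_id,
                 report = list(series = series_rep,
                               pairs = do.call(rbind, pair_rep))),
            class = "dcc_connectivity")
}

#' @export
print.dcc_connectivity <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("Dynamic connectivity for '%s': %d x %d x %d tensor\n",
              x$subject_id, d[1L], d[2L], d[3L]))
  cat(sprintf("  %d/%d pair fits converged\n",
              sum(x$report$pairs$converged), nrow(x$report$pairs)))
  invisible(x)
}

#' @export
plot.dcc_connectivity <- function(x, pair = c(1, 2), ...) {
  r <- x$tensor[pair[1L], pair[2L], ]
  graphics::plot(r, type = "l", ylim = c(-1, 1), xlab = "time point",
                 ylab = expression(r[t]),
                 main = sprintf("%s: dynamic correlation %s-%s", x$subject_id,
                                dimnames(x$tensor)[[1L]][pair[1L]],
                                dimnames(x$tensor)[[2L]][pair[2L]]), ...)
  invisible(x)
}
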