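# stage 1 of the DCC estimator: per-series GARCH(1,1) by Gaussian QMLE

garch_sigma2 <- function(omega, alpha, beta, x2, s2_init) {
  .garch_sigma2_c(omega, alpha, beta, x2, s2_init)
}

garch_nll <- function(par, x2, s2_init) {
  ab <- to_simplex(par[2:3])
  .garch_nll_c(exp(par[1L]), ab[1L], ab[2L], x2, s2_init)
}

#' Fit a GARCH(1,1) model by Gaussian quasi-maximum likelihood
#'
#' Estimates `sigma^2_t = omega + alpha * y^2_{t-1} + beta * sigma^2_{t-1}`
#' on a zero-mean series under the constraints `omega > 0`,
#' `alpha, beta >= 0`, `alpha + beta < 1` (enforced through a log/softmax
#' reparameterization, so the optimizer is unconstrained). The conditional
#' variance recursion is initialized at the sample variance. Several starting
#' points are tried and the best likelihood kept; non-convergence and
#' near-boundary solutions are flagged, never silently accepted.
#'
#' @param x numeric zero-mean series, length >= 50, non-constant.
#' @param starts number of optimizer starting points (default 3).
#' @param control passed to [stats::optim()] (Nelder-Mead); the default sets
#'   `reltol = 1e-8`.
#' @return An object of class `garch_fit` with components `coefficients`
#'   (`omega`, `alpha`, `beta`), `sigma_t` (conditional standard deviations,
#'   length T), `loglik`, `converged`, `boundary`, `n`, and the series `y`.
#' @seealso [fit_dcc_pair()] for stage 2, [simulate_garch_series()] for the
#'   matching generator.
#' @examples
#' y <- simulate_garch_series(0.1, 0.1, 0.8, 1000, seed = 1)
#' fit <- fit_garch(y)
#' coef(fit)
#' @export
fit_garch <- function(x, starts = 3, control = list(reltol = 1e-8)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 50L) stopf("fit_garch needs at least 50 observations (got %d)", n)
  v <- stats::var(x)
  if (!is.finite(v) || v < 1e-12) {
    stopf("degenerate input: series variance %.3g is below 1e-12", v)
  }
  if (abs(mean(x)) > 0.1 * sqrt(v)) {
    warnf("series mean is not close to zero; demean before fitting")
  }
  x2 <- x^2

  start_ab <- list(c(0.05, 0.90), c(0.10, 0.80), c(0.02, 0.50))
  start_ab <- start_ab[seq_len(min(starts, length(start_ab)))]
  fits <- list()
  for (ab in start_ab) {
    p0 <- c(log(v * (1 - sum(ab))), from_simplex(ab))
    opt <- try(stats::optim(p0, garch_nll, x2 = x2, s2_init = v,
                            method = "Nelder-Mead", control = control),
               silent = TRUE)
    if (!inherits(opt, "try-error")) fits <- c(fits, list(opt))
  }
  if (!length(fits)) stopf("GARCH optimization failed from every start")
  best <- pick_interior(fits)

  ab <- to_simplex(best$par[2:3])
  omega <- exp(best$par[1L])
  sig2 <- garch_sigma2(omega, ab[1L], ab[2L], x2, v)
  structure(list(
    coefficients = c(omega = omega, alpha = ab[1L], beta = ab[2L]),
    sigma_t = sqrt(sig2),
    loglik = -best$value,
    converged = best$convergence == 0 && all(is.finite(sig2)),
    boundary = sum(ab) >= 1 - 1e-6,
    n = n, y = x), class = "garch_fit")
}

#' @export
print.garch_fit <- function(x, digits = 4, ...) {
  cat("GARCH(1,1) Gaussian QML fit\n")
  print(round(x$coefficients, digits))
  cat(sprintf("logLik %.3f on %d obs; unconditional var %.4g%s%s\n",
              x$loglik, x$n,
              x$coefficients[1L] / (1 - x$coefficients[2L] - x$coefficients[3L]),
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$boundary) " [boundary: alpha + beta ~ 1]" else ""))
  invisible(x)
}

#' @export
logLik.garch_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' @export
fitted.garch_fit <- function(object, ...) object$sigma_t

#' @export
residuals.garch_fit <- function(object, ...) object$y / object$sigma_t

#' @export
simulate.garch_fit <- function(object, nsim = 1, seed = NULL, ...) {
  co <- object$coefficients
  replicate(nsim,
            simulate_garch_series(co[1L], co[2L], co[3L], object$n, seed = seed),
            simplify = FALSE)
}

#' @export
plot.garch_fit <- function(x, ...) {
  graphics::plot(x$sigma_t, type = "l", xlab = "time point",
                 ylab = expression(hat(sigma)[t]),
                 main = "Conditional standard deviation", ...)
  invisible(x)
}

#' Standardize a pair of series by their fitted conditional volatilities
#'
#' Computes `eps[i, t] = y[i, t] / sigma[i, t]`, the standardized residuals
#' feeding the correlation stage of the DCC estimator.
#'
#' @param pair numeric 2 x T matrix of zero-mean series.
#' @param fit1,fit2 `garch_fit` objects for rows 1 and 2.
#' @return A 2 x T matrix of standardized residuals.
#' @export
standardized_residuals <- function(pair, fit1, fit2) {
  stopifnot(is.matrix(pair), nrow(pair) == 2L,
            inherits(fit1, "garch_fit"), inherits(fit2, "garch_fit"))
  if (!fit1$converged || !fit2$converged) {
    warnf("standardizing with a non-converged GARCH fit")
  }
  s <- rbind(fit1$sigma_t, fit2$sigma_t)
  if (ncol(s) != ncol(pair)) stopf("fit length does not match the pair")
  if (any(s <= 0)) stopf("non-positive conditional standard deviation")
  pair / s
}
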