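# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  # deterministic child seed, kept inside 32-bit integer range
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647)
}

# map unconstrained pair p to (a, b) with a, b > 0 and a + b < 1
to_simplex <- function(p) {
  e <- exp(pmin(p, 35))
  e / (1 + sum(e))
}

from_simplex <- function(ab) {
  rest <- 1 - sum(ab)
  log(pmax(ab, 1e-10) / max(rest, 1e-10))
}

# among multi-start optima whose objectives are near-tied (a difference
# below 1 is negligible on the quasi-log-likelihood scale), prefer the
# solution farthest from the persistence boundary: on the alpha = 0 (or
# theta1 = 0) ridge the boundary solutions leave the stationary level
# ill-conditioned while fitting the data equally well
pick_interior <- function(fits, tie_tol = 1.0) {
  vals <- vapply(fits, `[[`, 0, "value")
  near <- fits[vals <= min(vals) + tie_tol]
  sums <- vapply(near, function(f) sum(to_simplex(f$par[length(f$par) - 1:0])), 0)
  near[[which.min(sums)]]
}

dccmst_log <- function(..., verbose = getOption("dccmst.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
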