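`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG seed, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Standard bivariate normal CDF P(Z1 <= h, Z2 <= k) with correlation rho,
# by quadrature over the conditional normal. Handles infinite bounds and
# the degenerate |rho| ~ 1 limits.
pbinorm <- function(h, k, rho) {
  if (is.infinite(h) && h > 0) return(stats::pnorm(k))
  if (is.infinite(k) && k > 0) return(stats::pnorm(h))
  if (is.infinite(h) || is.infinite(k)) return(0)
  if (rho >= 1 - 1e-12) return(stats::pnorm(min(h, k)))
  if (rho <= -1 + 1e-12) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  s <- sqrt(1 - rho^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((k - rho * z) / s)
  stats::integrate(f, -Inf, h, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

assert_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  x
}
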