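# Internal numerical and validation helpers.

#' Gauss-Hermite nodes and weights
#'
#' Nodes/weights for the physicists' Hermite weight exp(-x^2), computed by
#' the Golub-Welsch eigenvalue method.  For Z ~ N(mu, sigma^2),
#' E f(Z) = sum(w_k * f(mu + sigma * sqrt(2) * x_k)) / sqrt(pi).
#'
#' @param n number of nodes (>= 1)
#' @return list with numeric vectors `nodes` and `weights`
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  # Jacobi matrix for Hermite polynomials: zero diagonal, sqrt(i/2) off-diagonal
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- e$values[ord]
  weights <- sqrt(pi) * (e$vectors[1L, ord])^2
  list(nodes = nodes, weights = weights)
}

# E[f(N(mu, var))] by Gauss-Hermite quadrature; mu may be a vector.
gh_expect <- function(f, mu, var, n_nodes) {
  if (var <= 1e-14) return(f(mu))
  gh <- gauss_hermite(n_nodes)
  out <- numeric(length(mu))
  s <- sqrt(2 * var)
  for (k in seq_len(n_nodes)) {
    out <- out + gh$weights[k] * f(mu + s * gh$nodes[k])
  }
  out / sqrt(pi)
}

# One Dirichlet draw; zero entries of alpha yield exact zero shares.
rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha, rate = 1), 0)
  if (sum(g) <= 0) {
    # pathological underflow: fall back to the mean
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# stop() with a classed condition so callers/tests can distinguish
# validation failures from programming errors.
fail <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "saltshift_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    fail("saltshift_schema_error", "%s: missing column(s): %s",
         what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
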