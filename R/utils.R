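# internal helpers shared across modules

# Run `expr` under a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

# symmetric, unit diagonal, eigenvalues >= -tol
check_corr_matrix <- function(m, what = "correlation matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("%s must be a square matrix", what)
  }
  if (any(abs(m - t(m)) > tol)) stopf("%s must be symmetric", what)
  if (any(abs(diag(m) - 1) > tol)) stopf("%s must have unit diagonal", what)
  if (any(abs(m) > 1 + tol)) stopf("%s entries must lie in [-1, 1]", what)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stopf("%s is not positive semi-definite (min eigenvalue %.3g)",
          what, min(ev))
  }
  invisible(TRUE)
}

# draw n rows from N(0, sigma) via eigen decomposition; handles singular
# (rank-deficient) correlation matrices such as a target r of exactly 1
rmvnorm_eigen <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * ncol(sigma)), nrow = n)
  z %*% t(e$vectors %*% diag(sqrt(lam), nrow = length(lam)))
}
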