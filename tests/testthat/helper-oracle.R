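# Brute-force oracle for the penalized check-loss problem, independent of
# the interior-point solver: an optimum lies at a vertex where p+1 linearly
# independent hyperplanes from {residual_i = 0} and {beta_k = 0} intersect.
# Enumerates every such basis, solves the square system, and returns the
# smallest objective.
rqr_oracle <- function(y, X, tau, lambda) {
  n <- length(y)
  p <- if (is.null(X)) 0L else ncol(X)
  A <- cbind(rep(1, n), X)
  m <- p + 1L
  eq_lhs <- A
  eq_rhs <- y
  if (p > 0L) {
    eq_lhs <- rbind(eq_lhs, cbind(matrix(0, p, 1L), diag(p)))
    eq_rhs <- c(eq_rhs, rep(0, p))
  }
  best <- Inf
  for (cols in utils::combn(nrow(eq_lhs), m, simplify = FALSE)) {
    M <- eq_lhs[cols, , drop = FALSE]
    b <- tryCatch(solve(M, eq_rhs[cols]), error = function(e) NULL)
    if (is.null(b)) next
    res <- y - drop(A %*% b)
    obj <- sum(check_loss(res, tau)) + lambda * sum(abs(b[-1L]))
    if (obj < best) best <- obj
  }
  best
}

# LAD optimum by direct vertex enumeration on the sum of absolute residuals
lad_oracle <- function(y, X) {
  n <- length(y); p <- ncol(X)
  A <- cbind(1, X)
  best <- Inf
  for (cols in utils::combn(n, p + 1L, simplify = FALSE)) {
    b <- tryCatch(solve(A[cols, , drop = FALSE], y[cols]),
                  error = function(e) NULL)
    if (is.null(b)) next
    best <- min(best, sum(abs(y - drop(A %*% b))))
  }
  best
}

# random tiny RQR instance in the oracle-tractable regime
random_tiny_instance <- function() {
  n <- sample(3:8, 1L)
  p <- sample(0:2, 1L)
  list(
    y = round(rnorm(n, 0, 3), 4),
    X = if (p > 0L) matrix(sample(0:2, n * p, replace = TRUE), n, p) else NULL,
    tau = sample(c(0.2, 0.5, 0.8), 1L),
    lambda = sample(c(0, 0.5, 2), 1L)
  )
}
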