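#' Bootstrap standard errors and p-values for marker effects
#'
#' Case (paired) resampling of `(y_i, x_i.)` rows with replacement. Each
#' replicate refits [solve_rqr()] at the given quantile and penalty; the
#' per-marker standard error is the standard deviation of the bootstrap
#' coefficients and the two-sided p-value uses the normal approximation
#' `2 * (1 - pnorm(|beta| / se))`. A marker with zero bootstrap spread and a
#' zero point estimate gets `p = 1`; with a nonzero estimate, the p-value is
#' floored at machine-minimum rather than reported as exactly zero.
#'
#' @inheritParams solve_rqr
#' @param reps Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; identical seeds give bit-identical summaries.
#' @return Object of class `bootstrap_summary`: list with `table` (tibble of
#'   `marker_id`, `estimate`, `se`, `p_value`), `replicates` (`reps x p`
#'   matrix of bootstrap coefficients), `reps_used`, `seed`, `tau`, `lambda`.
#' @export
bootstrap_effects <- function(y, X, tau, lambda, reps = 200L, seed = 1L) {
  if (reps < 2L) abort("`reps` must be at least 2.", class = "growthqr_domain_error")
  X <- as.matrix(X)
  n <- length(y)
  point <- solve_rqr(y, X, tau, lambda)
  B <- withr::with_seed(as.integer(seed), {
    reps_beta <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      solve_rqr(y[idx], X[idx, , drop = FALSE], tau, lambda)$beta_hat
    }, numeric(ncol(X)))
    if (is.null(dim(reps_beta))) reps_beta <- rbind(reps_beta)
    t(reps_beta)
  })
  colnames(B) <- colnames(X)
  rownames(B) <- NULL
  ## snap interior-point rounding (~1e-12) to exact zero so that markers the
  ## penalty excludes in every replicate report se = 0, p = 1
  snap <- 1e-8 * max(1, mean(abs(y)))
  B[abs(B) < snap] <- 0
  est <- point$beta_hat
  est[abs(est) < snap] <- 0
  se <- apply(B, 2L, sd)
  p <- 2 * (1 - pnorm(abs(est) / se))
  p[se == 0 & abs(est) <= 1e-12] <- 1
  p[se == 0 & abs(est) > 1e-12] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  structure(
    list(table = tibble::tibble(marker_id = colnames(X), estimate = unname(est),
                                se = unname(se), p_value = unname(p)),
         replicates = B, reps_used = as.integer(reps), seed = as.integer(seed),
         tau = tau, lambda = lambda, point_fit = point),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> tau = %.2f, lambda = %g, %d replicates, %d markers\n",
              x$tau, x$lambda, x$reps_used, nrow(x$table)))
  invisible(x)
}
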