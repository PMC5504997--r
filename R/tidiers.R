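#' Tidy an RQR fit into a coefficient table
#'
#' @param x An `rqr_fit` from [solve_rqr()].
#' @param ... Unused.
#' @return Tibble with one row per term (`(Intercept)` first, then
#'   markers): `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.rqr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$beta_hat) %||%
               paste0("x", seq_along(x$beta_hat))),
    estimate = c(x$mu_hat, unname(x$beta_hat))
  )
}

#' One-row summary of an RQR fit
#'
#' @param x An `rqr_fit`.
#' @param ... Unused.
#' @return Tibble: `tau`, `lambda`, `objective`, `pseudo_r1`, `n_nonzero`,
#'   `iterations`, `n`.
#' @exportS3Method generics::glance
glance.rqr_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, lambda = x$lambda, objective = x$objective,
                 pseudo_r1 = x$pseudo_r1, n_nonzero = x$n_nonzero,
                 iterations = x$iterations, n = x$n)
}

#' Tidy a bootstrap summary
#'
#' @param x A `bootstrap_summary` from [bootstrap_effects()].
#' @param ... Unused.
#' @return Tibble: `marker_id`, `estimate`, `se`, `p_value`.
#' @exportS3Method generics::tidy
tidy.bootstrap_summary <- function(x, ...) x$table
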