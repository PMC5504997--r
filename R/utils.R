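## internal helpers shared across modules

traits <- c("alpha1", "alpha2", "alpha3")

stop_if_not_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "growthqr_domain_error")
  }
  bad <- if (open) (x <= 0 || x >= 1) else (x < 0 || x > 1)
  if (bad) {
    abort(sprintf("`%s` must lie strictly inside (0, 1), got %g.", name, x),
          class = "growthqr_domain_error")
  }
  invisible(x)
}

## sample tau-quantile that minimizes the check loss (left-continuous inverse cdf)
check_quantile <- function(y, tau) {
  unname(quantile(y, probs = tau, type = 1, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
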