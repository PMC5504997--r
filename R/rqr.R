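#' Check (pinball) loss
#'
#' Asymmetric absolute loss of quantile regression:
#' `tau * u` for a positive residual `u` and `-(1 - tau) * u` otherwise.
#' Non-negative, and zero only at `u = 0`.
#'
#' @param u Residual(s).
#' @param tau Quantile level, strictly inside (0, 1).
#' @return Loss value(s), same length as `u`.
#' @examples
#' check_loss(1, 0.2)   # 0.2
#' check_loss(-1, 0.2)  # 0.8
#' @export
check_loss <- function(u, tau) {
  stop_if_not_scalar_prob(tau, "tau")
  ifelse(u > 0, tau * u, -(1 - tau) * u)
}

#' L1-penalized quantile regression of marker effects
#'
#' Solves the regularized quantile regression (RQR) problem
#' \deqn{\hat\beta = \arg\min_{\mu,\beta} \sum_i \rho_\tau\big(y_i - \mu -
#'   x_i'\beta\big) + \lambda \sum_k |\beta_k|}
#' with an unpenalized intercept \eqn{\mu}. The convex problem is solved
#' exactly as a linear program by a primal-dual interior-point method
#' (Mehrotra predictor-corrector); the L1 penalty enters through the
#' standard augmentation that adds, per coefficient, two pseudo-observations
#' of zero with design weight \eqn{\pm\lambda}, whose pooled check loss
#' equals \eqn{\lambda|\beta_k|}.
#'
#' @param y Numeric response vector (corrected curve-parameter trait).
#' @param X Numeric matrix of genotype covariates (0/1/2), `n x p`; `p = 0`
#'   (zero columns) fits the intercept-only model. Genotypes enter raw,
#'   uncentered and unscaled.
#' @param tau Quantile level in (0, 1).
#' @param lambda Non-negative penalty.
#' @param tol Duality-gap tolerance (relative to the objective scale).
#' @param max_iter Iteration cap for the interior-point loop.
#' @return Object of class `rqr_fit`: list with `tau`, `lambda`, `mu_hat`,
#'   `beta_hat` (named by marker when `X` has column names), `fitted`,
#'   `residuals`, `objective` (attained penalized check loss), `pseudo_r1`,
#'   `n_nonzero` (coefficients with `|beta| > 1e-6`), `iterations`, `gap`.
#' @seealso [check_loss()], [select_lambda()], [bootstrap_effects()]
#' @export
solve_rqr <- function(y, X = NULL, tau = 0.5, lambda = 0,
                      tol = 1e-9, max_iter = 200L) {
  stop_if_not_scalar_prob(tau, "tau")
  if (lambda < 0) abort("`lambda` must be non-negative.", class = "growthqr_domain_error")
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0L) abort("Empty response.", class = "growthqr_domain_error")
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  if (nrow(X) != n) abort("`X` rows must match length(y).", class = "growthqr_domain_error")
  if (anyNA(X) || anyNA(y)) abort("Missing values in `y` or `X`.",
                                  class = "growthqr_domain_error")
  p <- ncol(X)

  A <- cbind(`(Intercept)` = 1, X)
  ya <- y
  if (p > 0L && lambda > 0) {
    ## pseudo-rows: rho_tau(-lambda*b_k) + rho_tau(lambda*b_k) = lambda*|b_k|
    P <- matrix(0, 2L * p, p + 1L)
    for (k in seq_len(p)) {
      P[2L * k - 1L, k + 1L] <- lambda
      P[2L * k, k + 1L] <- -lambda
    }
    A <- rbind(A, P)
    ya <- c(ya, rep(0, 2L * p))
  }
  sol <- qr_interior_point(ya, A, tau, tol = tol, max_iter = max_iter)
  b <- unname(sol$coefficients)
  mu_hat <- b[1L]
  beta <- b[-1L]
  names(beta) <- colnames(X)
  fitted <- drop(cbind(1, X) %*% b)
  res <- y - fitted
  objective <- sum(check_loss(res, tau)) + lambda * sum(abs(beta))
  fit <- structure(
    list(tau = tau, lambda = lambda, mu_hat = mu_hat, beta_hat = beta,
         fitted = fitted, residuals = res, objective = objective,
         pseudo_r1 = NA_real_, n_nonzero = sum(abs(beta) > 1e-6),
         iterations = sol$iterations, gap = sol$gap, n = n),
    class = "rqr_fit"
  )
  fit$pseudo_r1 <- tryCatch(pseudo_r1(fit, y, tau), error = function(e) NA_real_)
  fit
}

## Frisch-Newton primal-dual interior point for min_b sum rho_tau(y - A b).
## Dual: max y'd s.t. A'd = (1-tau) A'1, d in [0,1]^n (after shifting).
## Maintains exact primal feasibility u - v = y - Ab and exact dual equality,
## so the duality gap u's + v'a bounds the suboptimality of b directly.
qr_interior_point <- function(y, A, tau, tol = 1e-9, max_iter = 200L) {
  n <- nrow(A); m <- ncol(A)
  scale <- max(1, mean(abs(y)))
  ## starting point: LS coefficients, complementarity pairs strictly positive
  AtA <- crossprod(A)
  b <- tryCatch(solve(AtA + diag(1e-8 * max(diag(AtA)), m), crossprod(A, y)),
                error = function(e) matrix(0, m, 1))
  b <- drop(b)
  r <- y - drop(A %*% b)
  eps0 <- max(1e-4 * scale, 1e-8)
  u <- pmax(r, 0) + eps0
  v <- u - r
  a <- rep(1 - tau, n)
  s <- 1 - a

  gap <- sum(u * s) + sum(v * a)
  it <- 0L
  repeat {
    it <- it + 1L
    primal_obj <- tau * sum(u) + (1 - tau) * sum(v)
    if (gap < tol * (1 + primal_obj) || it > max_iter) break

    w <- 1 / (u / s + v / a)
    ## predictor (affine) direction: mu = 0, no cross terms
    g <- v - u
    db <- solve_spd(A, w, -crossprod(A, w * g))
    da <- -w * (drop(A %*% db) + g)
    ds <- -da
    du <- -u + (u / s) * da
    dv <- -v - (v / a) * da

    ap <- step_len(c(u, v), c(du, dv))
    ad <- step_len(c(a, s), c(da, ds))
    gap_aff <- sum((u + ap * du) * (s + ad * ds)) + sum((v + ap * dv) * (a + ad * da))
    mu <- (gap_aff / gap)^3 * gap / (2 * n)

    ## corrector with centering and second-order terms
    cu <- mu - u * s - du * ds
    cv <- mu - v * a - dv * da
    g2 <- cu / s - cv / a
    db <- solve_spd(A, w, -crossprod(A, w * g2))
    da <- -w * (drop(A %*% db) + g2)
    ds <- -da
    du <- cu / s + (u / s) * da
    dv <- cv / a - (v / a) * da

    ap <- step_len(c(u, v), c(du, dv))
    ad <- step_len(c(a, s), c(da, ds))
    if (ap < 1e-14 && ad < 1e-14) break
    b <- b + ap * db
    u <- u + ap * du
    v <- v + ap * dv
    a <- a + ad * da
    s <- s + ad * ds
    gap <- sum(u * s) + sum(v * a)
  }
  list(coefficients = b, iterations = it - 1L, gap = gap)
}

## solve (A' diag(w) A) x = rhs, with a tiny ridge fallback for rank deficiency
solve_spd <- function(A, w, rhs) {
  M <- crossprod(A, w * A)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(M + diag(1e-10 * (1 + max(diag(M))), ncol(M)))
  }
  drop(backsolve(ch, forwardsolve(t(ch), rhs)))
}

## largest alpha in (0,1] keeping x + alpha*dx > 0, damped by 0.9995
step_len <- function(x, dx) {
  neg <- dx < 0
  if (!any(neg)) return(1)
  min(1, 0.9995 * min(-x[neg] / dx[neg]))
}

#' @export
print.rqr_fit <- function(x, ...) {
  cat(sprintf(
    "<rqr_fit> tau = %.2f, lambda = %g: %d/%d nonzero effects, objective %.6g, pseudo-R1 %.3f\n",
    x$tau, x$lambda, x$n_nonzero, length(x$beta_hat), x$objective, x$pseudo_r1))
  invisible(x)
}

#' Quantile-fitting residual-sign diagnostic
#'
#' At the exact optimum of an unpenalized quantile regression the residual
#' signs bracket the quantile: (number of negative residuals) <= n*tau <=
#' (number of non-positive residuals). Residuals within `tol` of zero are
#' counted as zero, since interior-point solutions carry rounding at the
#' crossing observations.
#'
#' @param fit An `rqr_fit`.
#' @param tol Zero band for residual signs, relative to the response scale.
#' @return List with `n_negative`, `n_nonpositive`, `n_tau`, and `ok`.
#' @export
quantile_coverage <- function(fit, tol = 1e-6) {
  band <- tol * max(1, max(abs(fit$fitted)))
  r <- fit$residuals
  n_neg <- sum(r < -band)
  n_nonpos <- sum(r <= band)
  n_tau <- fit$n * fit$tau
  list(n_negative = n_neg, n_nonpositive = n_nonpos, n_tau = n_tau,
       ok = n_neg <= n_tau && n_tau <= n_nonpos)
}

#' Predictive capacity of a fitted model
#'
#' Pearson correlation between fitted and observed trait values, the
#' criterion used to choose the penalty.
#'
#' @param fit An `rqr_fit`.
#' @param y Observed response used in the fit.
#' @return Correlation in \[-1, 1\].
#' @export
predictive_capacity <- function(fit, y) {
  if (length(y) < 3L) abort("Need at least 3 observations.",
                            class = "growthqr_domain_error")
  if (sd(fit$fitted) < 1e-12 * max(1, mean(abs(y)))) {
    abort("Fitted values are constant; predictive capacity undefined.",
          class = "growthqr_undefined_capacity")
  }
  stats::cor(fit$fitted, y)
}

#' Koenker-Machado pseudo-R1 goodness of fit
#'
#' `1 - V_full / V_null`, where `V_full` is the check loss of the fitted
#' model and `V_null` the check loss of the intercept-only model (the sample
#' tau-quantile). Equals 1 for a perfect fit and 0 when the model does no
#' better than the marginal quantile.
#'
#' @param fit An `rqr_fit` (or any object with elements `fitted`).
#' @param y Observed response.
#' @param tau Quantile level.
#' @return Real number `<= 1`.
#' @export
pseudo_r1 <- function(fit, y, tau) {
  v_full <- sum(check_loss(y - fit$fitted, tau))
  v_null <- sum(check_loss(y - check_quantile(y, tau), tau))
  if (v_null <= 0) {
    abort("Constant response: pseudo-R1 undefined.", class = "growthqr_domain_error")
  }
  1 - v_full / v_null
}

#' Select the penalty by predictive capacity over a grid
#'
#' Fits [solve_rqr()] at every penalty in `grid` and returns the penalty
#' maximizing predictive capacity — by default the in-sample correlation of
#' fitted and observed values; `method = "cv"` uses k-fold cross-validated
#' correlation of out-of-fold predictions instead. Ties are broken toward
#' the largest penalty (sparser model). Penalties whose fit is constant
#' (capacity undefined) are rejected.
#'
#' @inheritParams solve_rqr
#' @param grid Ascending non-negative penalty values.
#' @param method `"insample"` (default) or `"cv"`.
#' @param folds Number of cross-validation folds when `method = "cv"`.
#' @param seed Seed for the fold assignment (only used for `"cv"`).
#' @return List with `lambda` (selected value), `fit` (refit at the selected
#'   penalty on all data), and `table` (tibble of `lambda`, `capacity`,
#'   `n_nonzero`).
#' @export
select_lambda <- function(y, X, tau, grid = seq(0, 50, by = 0.5),
                          method = c("insample", "cv"), folds = 5L, seed = 1L) {
  method <- match.arg(method)
  if (length(grid) == 0L) abort("Empty penalty grid.", class = "growthqr_domain_error")
  grid <- sort(grid)
  cap <- rep(NA_real_, length(grid))
  nnz <- rep(NA_integer_, length(grid))
  fits <- vector("list", length(grid))
  fold_id <- NULL
  if (method == "cv") {
    fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), length(y))))
  }
  for (i in seq_along(grid)) {
    fit <- solve_rqr(y, X, tau, grid[i])
    fits[[i]] <- fit
    nnz[i] <- fit$n_nonzero
    cap[i] <- tryCatch({
      if (method == "insample") {
        predictive_capacity(fit, y)
      } else {
        pred <- rep(NA_real_, length(y))
        for (f in seq_len(folds)) {
          hold <- fold_id == f
          ff <- solve_rqr(y[!hold], X[!hold, , drop = FALSE], tau, grid[i])
          pred[hold] <- ff$mu_hat + drop(X[hold, , drop = FALSE] %*% ff$beta_hat)
        }
        if (sd(pred) < 1e-12) abort("constant", class = "growthqr_undefined_capacity")
        stats::cor(pred, y)
      }
    }, growthqr_undefined_capacity = function(e) NA_real_)
  }
  if (all(is.na(cap))) {
    abort("Predictive capacity undefined at every penalty in the grid.",
          class = "growthqr_undefined_capacity")
  }
  ## ties toward the largest penalty: scan from the top of the grid
  best <- rev(which(cap == max(cap, na.rm = TRUE)))[1L]
  list(lambda = grid[best], fit = fits[[best]],
       table = tibble::tibble(lambda = grid, capacity = cap, n_nonzero = nnz))
}
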