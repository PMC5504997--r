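#' Logistic growth function
#'
#' Three-parameter logistic curve used throughout the package:
#' \deqn{w(t) = \alpha_1 / (1 + \exp[(\alpha_2 - t)/\alpha_3]).}
#' With `alpha3 > 0`, `alpha1` is the horizontal asymptote (mature weight,
#' kg), `alpha2` the age at the inflection point (days), where the response
#' equals `alpha1/2`, and `alpha3` a growth-scale parameter (days): the
#' distance on the age axis between the inflection point and the age where
#' the response reaches `alpha1/(1 + e^-1)`, about 73% of `alpha1`.
#' `alpha3` is the reciprocal of the growth-rate parameter of the rate-form
#' parameterization.
#'
#' @param age Age(s) in days; numeric vector.
#' @param alpha1 Mature weight (asymptote), kg.
#' @param alpha2 Inflection age, days.
#' @param alpha3 Growth scale, days; must be nonzero.
#' @return Predicted weight(s) in kg, recycled over the inputs.
#' @examples
#' logistic_predict(113, alpha1 = 90, alpha2 = 113, alpha3 = 32)  # 45 = 90/2
#' logistic_predict(113 + 32, 90, 113, 32) / 90                   # ~0.73
#' @export
logistic_predict <- function(age, alpha1, alpha2, alpha3) {
  if (any(alpha3 == 0)) {
    abort("`alpha3` must be nonzero.", class = "growthqr_domain_error")
  }
  alpha1 / (1 + exp((alpha2 - age) / alpha3))
}

## self-start values for the scale-form logistic on one weight-age series
logistic_init <- function(age, weight) {
  a1 <- 1.05 * max(weight)
  ## age at which the series crosses a1/2, by linear interpolation
  half <- a1 / 2
  if (all(weight < half)) {
    ## extrapolate from the last two points
    k <- length(age)
    slope <- (weight[k] - weight[k - 1L]) / (age[k] - age[k - 1L])
    a2 <- if (slope > 0) age[k] + (half - weight[k]) / slope else max(age)
  } else {
    i <- which(weight >= half)[1L]
    a2 <- if (i == 1L) age[1L] else {
      age[i - 1L] + (half - weight[i - 1L]) * (age[i] - age[i - 1L]) /
        (weight[i] - weight[i - 1L])
    }
  }
  ## slope of logit(w/a1) on age estimates 1/a3
  z <- pmin(pmax(weight / a1, 1e-6), 1 - 1e-6)
  lg <- log(z / (1 - z))
  b <- coef(lm(lg ~ age))[[2L]]
  a3 <- if (is.finite(b) && b > 1e-8) 1 / b else diff(range(age)) / 4
  c(alpha1 = a1, alpha2 = a2, alpha3 = a3)
}

#' Fit the logistic growth model to one animal's records
#'
#' Least-squares fit of [logistic_predict()] to a single weight-age series
#' by damped Gauss-Newton (Levenberg-Marquardt). Initialization sets
#' `alpha1` to 1.05 times the maximum observed weight, `alpha2` to the
#' interpolated age at half that asymptote, and `alpha3` from the slope of
#' `logit(weight/alpha1)` on age.
#'
#' @param age,weight Numeric vectors of equal length (days, kg); at least 4
#'   observations with strictly increasing ages and positive weights.
#' @param start Optional named vector `c(alpha1, alpha2, alpha3)` overriding
#'   the self-start.
#' @param tol Relative tolerance on the residual sum of squares; default 1e-8.
#' @param max_iter Maximum iterations; default 200.
#' @return One-row tibble: `alpha1`, `alpha2`, `alpha3`, `rss`, `converged`,
#'   `n_iter`. A fit whose `alpha1` falls outside `[max(weight),
#'   10*max(weight)]` is flagged `converged = FALSE`. Numerical failure
#'   (e.g. degenerate, curvature-free data) never raises: it returns the
#'   initialization with `converged = FALSE`.
#' @export
fit_logistic <- function(age, weight, start = NULL, tol = 1e-8, max_iter = 200L) {
  if (length(age) != length(weight)) {
    abort("`age` and `weight` must have equal length.", class = "growthqr_format_error")
  }
  if (length(age) < 4L) {
    abort("At least 4 observations are required for a 3-parameter fit.",
          class = "growthqr_insufficient_data")
  }
  if (any(weight <= 0)) {
    abort("Weights must be strictly positive.", class = "growthqr_domain_error")
  }
  if (anyDuplicated(age)) {
    abort("Duplicate ages within an animal.", class = "growthqr_domain_error")
  }
  o <- order(age)
  age <- unname(age[o]); weight <- unname(weight[o])
  init <- if (is.null(start)) logistic_init(age, weight) else start[traits]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      weight ~ alpha1 / (1 + exp((alpha2 - age) / alpha3)),
      data = data.frame(age = age, weight = weight),
      start = as.list(init),
      control = minpack.lm::nls.lm.control(ftol = tol, maxiter = as.integer(max_iter))
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(
      alpha1 = init[["alpha1"]], alpha2 = init[["alpha2"]], alpha3 = init[["alpha3"]],
      rss = sum((weight - logistic_predict(age, init[["alpha1"]], init[["alpha2"]],
                                           init[["alpha3"]]))^2),
      converged = FALSE, n_iter = 0L
    ))
  }
  p <- coef(fit)
  rss <- sum(resid(fit)^2)
  info <- fit$convInfo
  sane <- p[["alpha1"]] >= max(weight) && p[["alpha1"]] <= 10 * max(weight) &&
    p[["alpha3"]] > 0
  tibble::tibble(
    alpha1 = p[["alpha1"]], alpha2 = p[["alpha2"]], alpha3 = p[["alpha3"]],
    rss = rss,
    converged = isTRUE(info$isConv) && sane,
    n_iter = as.integer(info$finIter %||% NA_integer_)
  )
}

#' Fit logistic growth curves for every animal
#'
#' Maps [fit_logistic()] over a long-format table of weight-age records.
#'
#' @param records Data frame with columns `animal_id`, `age_days`,
#'   `weight_kg` (as returned by [read_phenotypes()] or
#'   [simulate_phenotypes()]).
#' @inheritParams fit_logistic
#' @return Tibble with one row per animal: `animal_id`, `alpha1`, `alpha2`,
#'   `alpha3`, `rss`, `converged`, `n_iter`.
#' @export
fit_growth_curves <- function(records, tol = 1e-8, max_iter = 200L) {
  records <- as_growth_records(records)
  out <- records |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(~ fit_logistic(.x$age_days, .x$weight_kg,
                                       tol = tol, max_iter = max_iter)) |>
    dplyr::ungroup()
  n_fail <- sum(!out$converged)
  if (n_fail > 0) {
    inform(sprintf("%d of %d curve fits did not converge.", n_fail, nrow(out)))
  }
  out
}

#' Correct curve parameters for fixed effects
#'
#' Regresses each estimated curve parameter on the categorical fixed effects
#' sex, lot, and halothane genotype (main effects, treatment coding) and
#' returns, per animal, the OLS residual plus the grand mean — so each
#' corrected trait keeps the mean of the raw estimates while the fixed-effect
#' differences are removed. Animals whose curve fit did not converge are
#' dropped with a message.
#'
#' @param params Tibble from [fit_growth_curves()].
#' @param covariates Data frame with columns `animal_id`, `sex`, `lot`,
#'   `halothane`; must cover every converged animal.
#' @return Tibble of class `adjusted_phenotypes` with columns `animal_id`,
#'   `alpha1`, `alpha2`, `alpha3` (corrected values). The per-trait grand
#'   means are attached as attribute `grand_means` and returned by
#'   [trait_means()].
#' @export
adjust_fixed_effects <- function(params, covariates) {
  keep <- params$converged %||% rep(TRUE, nrow(params))
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("Excluding %d non-converged animals from fixed-effect correction.",
                   n_drop))
  }
  params <- params[keep, , drop = FALSE]
  if (nrow(params) == 0L) {
    abort("No converged animals to correct.", class = "growthqr_insufficient_data")
  }
  missing_cov <- setdiff(params$animal_id, covariates$animal_id)
  if (length(missing_cov) > 0) {
    abort(sprintf("Covariates missing for animals: %s.",
                  paste(head(missing_cov, 5L), collapse = ", ")),
          class = "growthqr_format_error")
  }
  df <- dplyr::left_join(params, covariates, by = "animal_id")
  for (v in c("sex", "lot", "halothane")) df[[v]] <- factor(df[[v]])
  ## single-level factors carry no contrast; drop them from the model
  terms <- c("sex", "lot", "halothane")[vapply(
    c("sex", "lot", "halothane"), function(v) nlevels(df[[v]]) > 1L, logical(1))]
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  gm <- setNames(numeric(3), traits)
  out <- tibble::tibble(animal_id = df$animal_id)
  for (tr in traits) {
    fml <- stats::as.formula(paste(tr, "~", rhs))
    fit <- withCallingHandlers(
      lm(fml, data = df),
      warning = function(w) {
        warn(conditionMessage(w)); invokeRestart("muffleWarning")
      }
    )
    if (anyNA(coef(fit)) && rhs != "1") {
      warn(sprintf("Rank-deficient fixed-effect design for %s; aliased levels absorbed.", tr))
    }
    gm[[tr]] <- mean(df[[tr]])
    out[[tr]] <- unname(resid(fit)) + gm[[tr]]
  }
  structure(out, grand_means = gm, class = c("adjusted_phenotypes", class(out)))
}

#' Grand means of adjusted phenotypes
#'
#' @param x An `adjusted_phenotypes` tibble from [adjust_fixed_effects()].
#' @return Named numeric vector `c(alpha1, alpha2, alpha3)`.
#' @export
trait_means <- function(x) {
  gm <- attr(x, "grand_means", exact = TRUE)
  if (is.null(gm)) {
    gm <- vapply(traits, function(tr) mean(x[[tr]]), numeric(1))
  }
  gm
}
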