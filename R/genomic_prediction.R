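#' Genomic estimated breeding values at a quantile
#'
#' `GEBV(tau) = u_i = sum_k x_ik * beta_k(tau)` per trait: the
#' genotype-weighted sum of the estimated marker effects, in trait units.
#'
#' @param panel A [genotype_panel()].
#' @param fits Named list of `rqr_fit` objects (names `alpha1`, `alpha2`,
#'   `alpha3`), all at the same quantile, whose coefficients align with the
#'   panel's markers by marker id.
#' @return Tibble of class `gebv_set`: `animal_id`, `u_alpha1`, `u_alpha2`,
#'   `u_alpha3`, with the quantile in attribute `tau`.
#' @export
compute_gebv <- function(panel, fits) {
  need <- intersect(traits, names(fits))
  if (length(need) == 0L) abort("`fits` must be named by trait.",
                                class = "growthqr_format_error")
  tau <- unique(vapply(fits[need], function(f) f$tau, numeric(1)))
  if (length(tau) != 1L) {
    abort("All fits must share one quantile.", class = "growthqr_format_error")
  }
  out <- tibble::tibble(animal_id = panel$animal_ids)
  for (tr in need) {
    beta <- fits[[tr]]$beta_hat
    if (is.null(names(beta)) || !setequal(names(beta), panel$marker_ids)) {
      abort(sprintf("Marker mismatch between panel and %s fit.", tr),
            class = "growthqr_alignment_error")
    }
    out[[paste0("u_", tr)]] <- unname(drop(panel$calls %*% beta[panel$marker_ids]))
  }
  structure(out, tau = tau, class = c("gebv_set", class(out)))
}

#' Quantile-specific genomic growth curve
#'
#' Predicts each animal's weight trajectory from the logistic model with
#' GEBV-shifted parameters,
#' \deqn{\hat y_i(t) = \frac{\mu_1 + u_{1i}}{1 + \exp[((\mu_2 + u_{2i}) - t)
#'   /(\mu_3 + u_{3i})]},}
#' where the \eqn{\mu}s are the grand means of the adjusted traits and the
#' \eqn{u}s the animal's GEBVs, and averages over animals. Animals whose
#' shifted growth scale `mu_3 + u_3` is zero (or negative, flipping the
#' asymptote interpretation) are excluded from the mean with a warning.
#'
#' @param means Named vector `c(alpha1, alpha2, alpha3)` of trait grand
#'   means, e.g. [trait_means()] of the adjusted phenotypes.
#' @param gebvs A `gebv_set` from [compute_gebv()] (missing `u_` columns are
#'   treated as zero).
#' @param ages Evaluation ages in days.
#' @return Tibble of class `genomic_curve`: `tau`, `age`, `mean`; the
#'   per-animal curve matrix (animals x ages) is attached as attribute
#'   `per_animal`.
#' @export
genomic_curve <- function(means, gebvs, ages = seq(0, 150, by = 5)) {
  stopifnot(all(traits %in% names(means)))
  n <- nrow(gebvs)
  u <- sapply(paste0("u_", traits), function(cl) {
    if (cl %in% names(gebvs)) gebvs[[cl]] else rep(0, n)
  })
  if (n == 1L) u <- matrix(u, nrow = 1L, dimnames = list(NULL, paste0("u_", traits)))
  a1 <- means[["alpha1"]] + u[, "u_alpha1"]
  a2 <- means[["alpha2"]] + u[, "u_alpha2"]
  a3 <- means[["alpha3"]] + u[, "u_alpha3"]
  ok <- a3 > 0
  if (!all(ok)) {
    warn(sprintf("Excluding %d animal(s) with non-positive shifted growth scale.",
                 sum(!ok)))
  }
  if (!any(ok)) abort("No animals with a valid shifted growth scale.",
                      class = "growthqr_domain_error")
  per <- matrix(NA_real_, sum(ok), length(ages))
  idx <- which(ok)
  for (j in seq_along(ages)) {
    per[, j] <- logistic_predict(ages[j], a1[idx], a2[idx], a3[idx])
  }
  rownames(per) <- gebvs$animal_id[idx]
  out <- tibble::tibble(
    tau = attr(gebvs, "tau", exact = TRUE) %||% NA_real_,
    age = ages,
    mean = colMeans(per)
  )
  structure(out, per_animal = per, class = c("genomic_curve", class(out)))
}

#' Rank the most relevant markers
#'
#' Orders markers by descending absolute estimated effect and keeps the top
#' `ceiling(fraction * p)`, annotated with bootstrap standard errors and
#' p-values (when supplied) and map position. Ties in `|effect|` at the
#' cutoff are broken by ascending marker index (panel order).
#'
#' @param fit An `rqr_fit` with named coefficients.
#' @param map Marker map tibble (`marker_id`, `chr`, `pos_cM`).
#' @param boot Optional `bootstrap_summary` for the same fit.
#' @param fraction Fraction of markers to keep, in (0, 1]; default 0.025
#'   (the "2.5% most relevant" convention, 6 of 237 markers).
#' @return Tibble: `rank`, `marker_id`, `effect`, `effect_abs`, `se`,
#'   `p_value`, `chr`, `pos_cM`, ordered by descending `effect_abs`.
#' @export
rank_markers <- function(fit, map, boot = NULL, fraction = 0.025) {
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].", class = "growthqr_domain_error")
  }
  beta <- fit$beta_hat
  p <- length(beta)
  if (p == 0L) abort("Fit has no marker effects.", class = "growthqr_domain_error")
  k <- ceiling(fraction * p)
  ord <- order(-abs(beta), seq_len(p))
  top <- ord[seq_len(k)]
  out <- tibble::tibble(
    rank = seq_len(k),
    marker_id = names(beta)[top],
    effect = unname(beta[top]),
    effect_abs = abs(unname(beta[top]))
  )
  if (!is.null(boot)) {
    out <- dplyr::left_join(out, boot$table[c("marker_id", "se", "p_value")],
                            by = "marker_id")
  } else {
    out$se <- NA_real_
    out$p_value <- NA_real_
  }
  dplyr::left_join(out, tibble::as_tibble(map)[c("marker_id", "chr", "pos_cM")],
                   by = "marker_id")
}

#' Bootstrap confidence band for the mean genomic curve
#'
#' For each bootstrap replicate of the marker effects, recomputes the GEBVs
#' and the mean genomic curve; the band at each age is the percentile
#' interval of the replicate mean curves.
#'
#' @param boots Named list (by trait) of `bootstrap_summary` objects sharing
#'   one quantile and replicate count; traits missing from the list
#'   contribute zero GEBVs.
#' @param panel A [genotype_panel()].
#' @param means Trait grand means as in [genomic_curve()].
#' @param ages Evaluation ages.
#' @param level Coverage level of the percentile interval, default 0.95.
#' @return Tibble of class `genomic_curve` with columns `tau`, `age`,
#'   `mean` (curve at the point estimates), `low`, `high`.
#' @export
curve_confidence_band <- function(boots, panel, means,
                                  ages = seq(0, 150, by = 5), level = 0.95) {
  need <- intersect(traits, names(boots))
  if (length(need) == 0L) abort("`boots` must be named by trait.",
                                class = "growthqr_format_error")
  reps <- unique(vapply(boots[need], function(b) b$reps_used, integer(1)))
  if (length(reps) != 1L || reps < 2L) {
    abort("All traits need the same number (>= 2) of bootstrap replicates.",
          class = "growthqr_domain_error")
  }
  tau <- boots[[need[1L]]]$tau
  n <- length(panel$animal_ids)
  rep_means <- matrix(NA_real_, reps, length(ages))
  for (r in seq_len(reps)) {
    g <- tibble::tibble(animal_id = panel$animal_ids)
    for (tr in need) {
      beta <- boots[[tr]]$replicates[r, panel$marker_ids]
      g[[paste0("u_", tr)]] <- drop(panel$calls %*% beta)
    }
    attr(g, "tau") <- tau
    crv <- suppressWarnings(genomic_curve(means, g, ages))
    rep_means[r, ] <- crv$mean
  }
  alpha <- (1 - level) / 2
  point <- compute_gebv(panel, lapply(boots[need], function(b) b$point_fit) |>
                          setNames(need))
  center <- genomic_curve(means, point, ages)
  lo <- apply(rep_means, 2L, quantile, probs = alpha, names = FALSE)
  hi <- apply(rep_means, 2L, quantile, probs = 1 - alpha, names = FALSE)
  ## the band always contains the point-estimate curve
  out <- tibble::tibble(
    tau = tau, age = ages, mean = center$mean,
    low = pmin(lo, center$mean), high = pmax(hi, center$mean)
  )
  structure(out, per_replicate = rep_means,
            class = c("genomic_curve", class(out)))
}
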