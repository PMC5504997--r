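#' Run the full two-step genomic growth-curve analysis
#'
#' Step one fits the logistic growth model per animal and corrects the
#' parameter estimates for sex, lot and halothane genotype. Step two, for
#' each quantile and each corrected trait, selects the L1 penalty over the
#' configured grid by predictive capacity, fits the regularized quantile
#' regression, bootstraps the marker effects, ranks the most relevant
#' markers, and builds the quantile-specific genomic growth curve with its
#' bootstrap confidence band.
#'
#' @param records Weight-age table (see [as_growth_records()]).
#' @param panel A [genotype_panel()].
#' @param covariates Tibble with `animal_id`, `sex`, `lot`, `halothane`.
#' @param config A [growthqr_config()].
#' @param bootstrap Logical; set `FALSE` to skip bootstrap inference (ranked
#'   markers then carry `NA` standard errors and no curve bands).
#' @return List of class `growthqr_run`:
#'   * `curve_params`: per-animal logistic fits;
#'   * `adjusted`: corrected trait values (with grand means);
#'   * `fits`: nested list `fits[[tau]][[trait]]` of `rqr_fit` objects;
#'   * `lambda_tables`: capacity-per-penalty tables, same nesting;
#'   * `summary`: tibble (trait, tau, lambda, capacity, pseudo_r1, n_nonzero);
#'   * `ranked`: tibble of top markers per (trait, tau);
#'   * `gebvs`: list by tau of [compute_gebv()] results;
#'   * `curves`: tibble of genomic mean curves (with bands if bootstrapped).
#' @export
growthqr_run <- function(records, panel, covariates,
                         config = growthqr_config(), bootstrap = TRUE) {
  curve_params <- fit_growth_curves(records)
  adjusted <- adjust_fixed_effects(curve_params, covariates)
  ## align animals: keep genotyped, converged animals in panel order
  keep <- intersect(panel$animal_ids, adjusted$animal_id)
  if (length(keep) < 3L) {
    abort("Fewer than 3 animals with both genotypes and converged fits.",
          class = "growthqr_insufficient_data")
  }
  adjusted_use <- adjusted[match(keep, adjusted$animal_id), ]
  X <- panel$calls[keep, , drop = FALSE]
  means <- trait_means(adjusted)

  fits <- list(); lambda_tables <- list(); boots <- list()
  summary_rows <- list(); ranked_rows <- list()
  gebvs <- list(); curve_rows <- list()
  for (tau in config$quantiles) {
    tkey <- format(tau)
    fits[[tkey]] <- list(); lambda_tables[[tkey]] <- list(); boots[[tkey]] <- list()
    for (tr in traits) {
      y <- adjusted_use[[tr]]
      sel <- select_lambda(y, X, tau, grid = config$lambda_grid)
      fit <- sel$fit
      fits[[tkey]][[tr]] <- fit
      lambda_tables[[tkey]][[tr]] <- sel$table
      cap <- sel$table$capacity[match(sel$lambda, sel$table$lambda)]
      inform(sprintf("tau=%.2f %s: lambda=%g, capacity=%.4f, pseudo-R1=%.4f, %d nonzero",
                     tau, tr, sel$lambda, cap, fit$pseudo_r1, fit$n_nonzero))
      boot <- NULL
      if (bootstrap) {
        boot <- bootstrap_effects(y, X, tau, sel$lambda,
                                  reps = config$bootstrap_reps,
                                  seed = config$seed + round(1000 * tau))
        boots[[tkey]][[tr]] <- boot
      }
      summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
        trait = tr, tau = tau, lambda = sel$lambda, capacity = cap,
        pseudo_r1 = fit$pseudo_r1, n_nonzero = fit$n_nonzero)
      rk <- rank_markers(fit, panel$map, boot = boot,
                         fraction = config$top_fraction)
      ranked_rows[[length(ranked_rows) + 1L]] <-
        dplyr::mutate(rk, trait = tr, tau = tau, .before = 1L)
    }
    gebvs[[tkey]] <- compute_gebv(panel, fits[[tkey]])
    if (bootstrap) {
      crv <- curve_confidence_band(boots[[tkey]], panel, means,
                                   ages = config$age_grid)
    } else {
      crv <- genomic_curve(means, gebvs[[tkey]], ages = config$age_grid)
      crv$low <- NA_real_; crv$high <- NA_real_
    }
    curve_rows[[length(curve_rows) + 1L]] <- tibble::as_tibble(crv)
  }
  structure(
    list(curve_params = curve_params, adjusted = adjusted, means = means,
         fits = fits, lambda_tables = lambda_tables,
         summary = dplyr::bind_rows(summary_rows),
         ranked = dplyr::bind_rows(ranked_rows),
         gebvs = gebvs, curves = dplyr::bind_rows(curve_rows),
         config = config),
    class = "growthqr_run"
  )
}

#' @export
print.growthqr_run <- function(x, ...) {
  cat(sprintf("<growthqr_run> %d animals, %d quantile(s)\n",
              nrow(x$adjusted), length(x$fits)))
  print(x$summary)
  invisible(x)
}

#' Write the standard report files for a pipeline run
#'
#' @param run A `growthqr_run`.
#' @param out_dir Output directory.
#' @return Invisibly, the written paths (see [write_report()]).
#' @export
report_run <- function(run, out_dir) {
  eff <- dplyr::select(run$ranked, dplyr::all_of(
    c("trait", "tau", "marker_id", "effect", "effect_abs", "se", "p_value",
      "chr", "pos_cM")))
  write_report(eff, run$summary, run$curves, out_dir)
}
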