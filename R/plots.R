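#' Plot a genomic growth curve
#'
#' Mean predicted weight trajectory at one quantile, with the bootstrap
#' confidence ribbon when the curve carries `low`/`high` columns.
#'
#' @param object A `genomic_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.genomic_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$mean))
  if (all(c("low", "high") %in% names(object)) && !all(is.na(object$low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$low, ymax = .data$high), alpha = 0.25)
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Age, d", y = "Predicted weight, kg",
                  title = sprintf("Genomic growth curve (tau = %.2f)",
                                  object$tau[1L]))
}

#' Compare genomic growth curves across quantiles
#'
#' @param curves Tibble of curves for several quantiles (e.g. the `curves`
#'   element of a [growthqr_run()]).
#' @return A ggplot object, one line (and optional ribbon) per quantile.
#' @export
plot_genomic_curves <- function(curves) {
  curves <- dplyr::mutate(curves, tau = factor(.data$tau))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$age, y = .data$mean,
                                            colour = .data$tau, fill = .data$tau))
  if (all(c("low", "high") %in% names(curves)) && !all(is.na(curves$low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$low, ymax = .data$high),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Age, d", y = "Predicted weight, kg",
                  colour = "Quantile", fill = "Quantile")
}

#' Plot marker effects along the genome
#'
#' Absolute estimated effects by map position, faceted by chromosome.
#'
#' @param fit An `rqr_fit` with named coefficients.
#' @param map Marker map (`marker_id`, `chr`, `pos_cM`).
#' @return A ggplot object.
#' @export
plot_marker_effects <- function(fit, map) {
  df <- tibble::tibble(marker_id = names(fit$beta_hat),
                       effect_abs = abs(unname(fit$beta_hat))) |>
    dplyr::left_join(tibble::as_tibble(map), by = "marker_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cM, y = .data$effect_abs)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos_cM, yend = 0)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chr), scales = "free_x") +
    ggplot2::labs(x = "Position, cM", y = "|Estimated effect|",
                  title = sprintf("Marker effects (tau = %.2f, lambda = %g)",
                                  fit$tau, fit$lambda))
}
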