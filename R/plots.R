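#' Plot a fitted correlogram with its bootstrap band
#'
#' The fitted correlation-by-distance curve (bootstrap median, solid) with
#' its 95% envelope, over the model-free pairwise correlations sized by
#' the number of overlapping years.
#'
#' @param fit A `synchrony_fit` from [fit_synchrony_boot()].
#' @param pairs Optional tibble from [pairwise_empirical_correlations()].
#' @param distances Distance grid in km.
#' @return A ggplot object.
#' @export
plot_correlogram <- function(fit, pairs = NULL,
                             distances = seq(0, 2000, by = 25)) {
  curve <- correlogram_curve(fit, distances)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$distance_km)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_correlation_median),
                       color = "steelblue", linewidth = 0.9) +
    ggplot2::labs(x = "Distance (km)", y = "Correlation") +
    ggplot2::coord_cartesian(ylim = c(-0.5, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(pairs) && nrow(pairs)) {
    p <- p + ggplot2::geom_point(
      data = pairs,
      ggplot2::aes(x = .data$distance_km, y = .data$pearson_r,
                   size = .data$n_overlap),
      color = "grey50", alpha = 0.5, show.legend = FALSE)
  }
  p
}

#' Plot synchrony before and after climate adjustment
#'
#' Raw (dashed) and climate-adjusted (solid) fitted correlograms with
#' their bootstrap bands; a gap between the curves is the synchrony
#' attributable to the climate variable.
#'
#' @param cmp A `synchrony_comparison` from [compare_synchrony()].
#' @return A ggplot object.
#' @export
plot_synchrony_comparison <- function(cmp) {
  stopifnot(inherits(cmp, "synchrony_comparison"))
  distances <- cmp$delta_curve$distance_km
  both <- dplyr::bind_rows(
    dplyr::mutate(correlogram_curve(cmp$raw_fit, distances), which = "raw"),
    dplyr::mutate(correlogram_curve(cmp$adjusted_fit, distances),
                  which = paste0("adjusted (", cmp$climate_variable, ")")))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$distance_km,
                                     color = .data$which,
                                     fill = .data$which)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_correlation_median,
                                    linetype = .data$which),
                       linewidth = 0.9) +
    ggplot2::labs(x = "Distance (km)", y = "Correlation",
                  color = NULL, fill = NULL, linetype = NULL) +
    ggplot2::coord_cartesian(ylim = c(-0.25, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
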