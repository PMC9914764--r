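#' Plot a fitted shelf-life surface
#'
#' Since packaging is a three-level factor, the surface reduces to three
#' quadratic profiles of predicted shelf-life against the residue rate,
#' drawn with the measured runs overlaid.
#'
#' @param object a `shelf_fit`.
#' @param rate_steps resolution of the rate axis.
#' @param ... unused.
#' @return A ggplot object.
#' @examples
#' autoplot(fit_shelf_life(study_shelf_life("OLPR", "ambient")))
#' @method autoplot shelf_fit
#' @export
autoplot.shelf_fit <- function(object, rate_steps = 100, ...) {
  grid <- surface_grid(object, rate_steps = rate_steps)
  measured <- augment(object)
  ggplot(grid, aes(x = .data$rate, y = .data$predicted,
                   colour = .data$packaging)) +
    geom_line(linewidth = 0.8) +
    geom_point(
      data = measured,
      aes(y = .data[[object$model$response]]),
      shape = 1, size = 2
    ) +
    labs(
      x = "residue incorporation rate (fraction of substrate)",
      y = sprintf("predicted shelf-life (%s)", object$model$response),
      colour = "packaging"
    ) +
    theme_minimal()
}

#' Plot total-microbial-count trajectories
#'
#' Log-scale growth curves per series with the contamination band edges as
#' horizontal guides.
#'
#' @param data a long-format TMC tibble (see [study_tmc()]).
#' @return A ggplot object.
#' @export
plot_tmc_series <- function(data) {
  ggplot(data, aes(x = .data$day, y = .data$log_cfu_g,
                   group = interaction(.data$packaging, .data$substrate_code),
                   colour = .data$packaging)) +
    geom_line(alpha = 0.7) +
    geom_hline(yintercept = tmc_band_edges, linetype = "dashed",
               colour = "grey40") +
    labs(x = "storage day", y = "total microbial count (log10 CFU/g)",
         colour = "packaging") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
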