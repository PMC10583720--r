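# ggplot2 visualisations of estimates and bounds

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cross-effect point estimates
#'
#' Dot plot of the plug-in estimates returned by [cross_effects()], with a
#' dashed reference line at the null.
#'
#' @param object A `crossmed_effects` tibble.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot crossmed_effects
#' @export
autoplot.crossmed_effects <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate, y = .data$estimand)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "effect estimate (risk difference scale)",
                  y = NULL,
                  title = "Cross direct effects, g-formula plug-in") +
    ggplot2::theme_minimal()
}

#' Plot bound intervals
#'
#' Line-range plot of the intervals returned by [cross_bounds()], one row per
#' estimand (colour-split by method when both are present).
#'
#' @param object A `crossmed_bounds` tibble.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot crossmed_bounds
#' @export
autoplot.crossmed_bounds <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(y = .data$estimand, xmin = .data$lower, xmax = .data$upper,
                 colour = .data$method)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_linerange(position = ggplot2::position_dodge(width = 0.4),
                            linewidth = 1) +
    ggplot2::labs(x = "bounds on the effect (risk difference scale)",
                  y = NULL,
                  title = "Bounds under residual mediator-outcome confounding") +
    ggplot2::theme_minimal()
}

#' Combined estimate-and-bounds panel
#'
#' Overlays plug-in estimates (with bootstrap intervals if supplied) on the
#' bound intervals, mirroring the usual presentation of partially identified
#' mediation effects.
#'
#' @param effects A `crossmed_effects` tibble.
#' @param bounds A `crossmed_bounds` tibble for the same estimands.
#' @param cis Optional tibble with columns `estimand`, `lower`, `upper`
#'   (bootstrap intervals for the point estimates).
#' @returns A ggplot object.
#' @export
plot_effects_with_bounds <- function(effects, bounds, cis = NULL) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_linerange(
      data = bounds,
      ggplot2::aes(y = .data$estimand, xmin = .data$lower,
                   xmax = .data$upper),
      colour = "steelblue", linewidth = 1.2, alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = effects,
      ggplot2::aes(y = .data$estimand, x = .data$estimate),
      size = 2
    )
  if (!is.null(cis)) {
    p <- p + ggplot2::geom_errorbarh(
      data = cis,
      ggplot2::aes(y = .data$estimand, xmin = .data$lower,
                   xmax = .data$upper),
      height = 0.15
    )
  }
  p + ggplot2::labs(x = "effect (risk difference scale)", y = NULL,
                    title = "Point estimates and nonparametric bounds") +
    ggplot2::theme_minimal()
}
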