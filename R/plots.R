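# ggplot2 views of the main result types.

#' Plot a kinetic fit over its data
#'
#' @param object A `kinetic_fit`.
#' @param log_x Log-scale the concentration axis (useful for biphasic
#'   curves spanning decades)?
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fit <- function(object, log_x = object$model == "two-site",
                                 ...) {
  curve <- object$data
  grid <- tibble(substrate_uM = exp(seq(
    log(max(min(curve$substrate_uM), 1e-3)),
    log(max(curve$substrate_uM)), length.out = 200)))
  grid$rate_per_s <- stats::predict(object$fit, newdata = grid)
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$substrate_uM, .data$rate_per_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "substrate (uM)", y = "turnover (1/s)",
                  title = sprintf("%s Michaelis-Menten fit", object$model))
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a melting fit with its midpoint
#'
#' @param object A `melting_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.melting_fit <- function(object, ...) {
  curve <- object$data
  grid <- tibble(temperature_C = seq(min(curve$temperature_C),
                                     max(curve$temperature_C),
                                     length.out = 200))
  grid$signal <- object$predict_fn(grid$temperature_C)
  ggplot2::ggplot(curve, ggplot2::aes(.data$temperature_C, .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$tm_C, linetype = "dashed") +
    ggplot2::labs(x = "temperature (degC)", y = "signal",
                  title = sprintf("Tm = %.1f degC", object$tm_C))
}

#' Per-site reconstruction-confidence profile
#'
#' @param post A `posterior_matrix`.
#' @return A ggplot object: per-site maximum posterior along the alignment,
#'   masked sites omitted.
#' @export
plot_confidence_profile <- function(post) {
  df <- tibble(site = seq_along(post$max_posterior),
               max_posterior = post$max_posterior) %>%
    filter(!is.na(.data$max_posterior))
  ggplot2::ggplot(df, ggplot2::aes(.data$site, .data$max_posterior)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_hline(yintercept = mean(df$max_posterior),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "alignment column", y = "max posterior",
                  title = sprintf("node %s (mean %.2f)", post$node,
                                  mean(df$max_posterior)))
}

#' Relative catalytic-efficiency heatmap
#'
#' @param profile Output of [relative_efficiency_profile()].
#' @return A ggplot object: enzymes x substrates tile plot of relative
#'   efficiencies (max per substrate = 100%).
#' @export
plot_relative_efficiency <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$enzyme, .data$substrate,
                                        fill = .data$relative_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", .data$relative_pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100), name = "% of max") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "relative catalytic efficiency by substrate")
}
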