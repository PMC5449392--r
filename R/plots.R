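#' Degree-distribution plot on log-log axes
#'
#' Plots the fraction of nodes at each degree on log-log axes with the
#' fitted power-law line overlaid (see [fit_power_law()]); a straight-line
#' trend is the visual signature of a scale-free network.
#'
#' @param net A `gene_network`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(net) {
  h <- degree_distribution_tbl(net)
  fit <- tryCatch(fit_power_law(h), error = function(e) NULL)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$degree, y = .data$fraction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree K", y = "P(K)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    line <- tibble::tibble(
      degree = h$degree,
      fraction = exp(fit$intercept) * h$degree^(-fit$exponent))
    p <- p +
      ggplot2::geom_line(data = line, colour = "grey40", linetype = "dashed") +
      ggplot2::labs(subtitle = sprintf("fitted exponent %.3f", fit$exponent))
  }
  p
}

#' @rdname precision_table
#' @param object A precision table (the tibble returned by
#'   [precision_table()]).
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.precision_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fraction, y = .data$precision,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "top-ranked fraction", y = "precision (%)",
                  colour = "ranking") +
    ggplot2::theme_minimal()
}
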