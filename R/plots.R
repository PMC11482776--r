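#' Plot the hybrid utility cloud of a screening result
#'
#' Scatter of the two marginal utilities, coloured by isolation-forest
#' anomaly score, with the selected features highlighted: anomalous
#' (outcome-associated) features sit away from the noise bulk near the
#' origin.
#'
#' @param object An `hfs_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hfs_screen
#' @export
autoplot.hfs_screen <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho1, y = .data$rho2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$anomaly,
                                     shape = .data$selected), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(
      x = "polynomial utility (adjusted R²)",
      y = "kernel partial correlation",
      colour = "anomaly score", shape = paste0("s ≥ ", object$tau),
      title = "Hybrid screening utilities"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the importance table of a fitted pipeline
#'
#' Bar chart of -log10 p-values of the tested features, with the
#' significance cutoff marked.
#'
#' @param object A [hifit()] result.
#' @param top Show at most this many features (by p-value).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hifit_result
#' @export
autoplot.hifit_result <- function(object, top = 30, ...) {
  d <- dplyr::slice_min(tidy(object), .data$p, n = top, with_ties = FALSE)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  d$neglogp <- -log10(pmax(d$p, 1e-16))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$neglogp, y = .data$feature,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(object$config$p_cutoff),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  fill = "selected",
                  title = "Permutation feature importance") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hifit_result
#' @param x A [hifit()] result.
#' @param y Unused.
#' @export
plot.hifit_result <- function(x, y, ...) print(autoplot(x, ...))

#' @rdname autoplot.hfs_screen
#' @param x An `hfs_screen` object.
#' @param y Unused.
#' @export
plot.hfs_screen <- function(x, y, ...) print(autoplot(x, ...))
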