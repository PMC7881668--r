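#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed-versus-predicted scatter plot
#'
#' Training and validation compounds against the line of perfect agreement.
#'
#' @param object A `kw_report` from [kw_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kw_report <- function(object, ...) {
  preds <- attr(object, "predictions")
  ggplot2::ggplot(preds,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Observed", y = "Predicted", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Williams plot (leverage versus standardized residual)
#'
#' @param object A `kw_ad` table from [williams_table()].
#' @param ... Unused.
#' @return A ggplot object with the critical-leverage and residual-band
#'   reference lines.
#' @export
autoplot.kw_ad <- function(object, ...) {
  band <- attr(object, "residual_band")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$leverage,
                               y = .data$standardized_residual,
                               colour = .data$split)) +
    ggplot2::geom_hline(yintercept = c(-band, band), linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = attr(object, "h_star"), linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Leverage", y = "Standardized residual",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Y-scrambling histogram
#'
#' Distribution of calibration R2 over the permuted models with the
#' unscrambled R2 marked.
#'
#' @param object A `kw_scramble` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kw_scramble <- function(object, ...) {
  perm <- tibble::as_tibble(object)[object$permutation > 0, ]
  ggplot2::ggplot(perm, ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = attr(object, "true_r2"),
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = expression(R^2 ~ "of scrambled models", ),
                  y = "Count") +
    ggplot2::theme_minimal()
}

#' PCA biplot
#'
#' Component scores with correlation-scaled loading vectors overlaid.
#'
#' @param object A `kw_pca` object.
#' @param scale_arrows Multiplier applied to the loading vectors for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kw_pca <- function(object, scale_arrows = NULL, ...) {
  sc <- object$scores
  lo <- object$loadings
  scale_arrows <- scale_arrows %||%
    (max(abs(c(sc$PC1, sc$PC2))) / max(abs(as.matrix(lo[, c("PC1", "PC2")]))))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$split), alpha = 0.6) +
    ggplot2::geom_segment(
      data = lo,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * scale_arrows,
                   yend = .data$PC2 * scale_arrows),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.02, "npc")),
      colour = "firebrick"
    ) +
    ggplot2::geom_text(
      data = lo,
      ggplot2::aes(x = .data$PC1 * scale_arrows * 1.08,
                   y = .data$PC2 * scale_arrows * 1.08,
                   label = .data$variable),
      colour = "firebrick", size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained$proportion[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained$proportion[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
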