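# ggplot2 views of the main result types.

#' Plot a 2D chromatin embedding
#'
#' Scatter of the embedded bins, optionally colored by a per-bin value
#' (signal, contact count to a viewpoint, or Moran quadrant).
#'
#' @param object An `embedding2d`.
#' @param color Optional vector (length = bins embedded) mapped to color.
#' @param color_name Legend title.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.embedding2d <- function(object, color = NULL,
                                 color_name = "value", ...) {
  df <- object$coords
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (is.null(color)) {
    p <- p + ggplot2::geom_point(size = 1.2)
  } else {
    df$color <- color
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          color = .data$color)) +
      ggplot2::geom_point(size = 1.5) +
      ggplot2::labs(color = color_name)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "KK x", y = "KK y")
}

#' Moran scatter and quadrant map of a spatial analysis
#'
#' Local Moran scatter (signal vs spatial lag, quadrant-colored); the
#' standard companion to the quadrant-colored embedding.
#'
#' @param object A `moran_result` from [moran_analysis()].
#' @param alpha Significance threshold highlighted in the plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moran_result <- function(object, alpha = 0.05, ...) {
  df <- object$local
  df$significant <- !is.na(df$p_sim) & df$p_sim <= alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$lag,
                                   color = .data$quadrant,
                                   shape = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "signal (centered)", y = "spatial lag",
                  title = sprintf("Global I = %.3f (p = %.3g)",
                                  object$global$I, object$global$p_value))
}

#' Heatmap of an aggregated APA matrix
#' @param object An `apa_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.apa_result <- function(object, ...) {
  m <- object$agg_matrix
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("APA score %.2f, ratio %.2f",
                                  object$apa_score, object$apa_ratio),
                  x = NULL, y = NULL)
}

#' QQ plot of empirical motif-pair p-values
#'
#' Expected vs observed -log10 p under the uniform null; well-calibrated
#' bootstrap p-values lie along the diagonal.
#'
#' @param results Pair-result tibble with `p_empirical`.
#' @return A ggplot.
#' @export
plot_pair_qq <- function(results) {
  p <- sort(results$p_empirical)
  df <- tibble(expected = -log10((seq_along(p) - 0.5) / length(p)),
               observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "expected -log10 p", y = "observed -log10 p")
}

#' Heatmap of cross-sample motif-pair significance proportions
#' @param summary_tbl Output of [cross_sample_summary()].
#' @return A ggplot.
#' @export
plot_pair_heatmap <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$motif_a, y = .data$motif_b,
                               fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(fill = "prop. significant")
}
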