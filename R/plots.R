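#' Scatter of methylation level against entropy
#'
#' The classic diagnostic of a mixed methylome: entropy is bounded by the
#' level, homogeneous segments sit on the floor, and cell-subset-specific
#' segments appear as intermediate-level points far below the stochastic
#' arc.
#'
#' @param stats segment tibble with `level` and `entropy` columns.
#' @param alpha point transparency.
#' @return a ggplot object.
#' @export
plot_level_entropy <- function(stats, alpha = 0.4) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$level, y = .data$entropy)) +
    ggplot2::geom_point(alpha = alpha, size = 0.8) +
    ggplot2::labs(x = "methylation level", y = "methylation entropy") +
    ggplot2::theme_minimal()
}

#' Histogram of segment methylation levels
#'
#' Whole-genome bisulfite data typically show a bimodal distribution with
#' most segments nearly unmethylated or nearly fully methylated.
#'
#' @inheritParams plot_level_entropy
#' @param bins histogram bin count (default 20).
#' @return a ggplot object.
#' @export
plot_level_histogram <- function(stats, bins = 20) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$level)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey30") +
    ggplot2::labs(x = "methylation level", y = "segments") +
    ggplot2::theme_minimal()
}

#' Entropy distribution per genomic feature class
#'
#' @param assigned output of [assign_segments()] with an `entropy` column.
#' @return a ggplot object (boxplots per class).
#' @export
plot_feature_entropy <- function(assigned) {
  ggplot2::ggplot(assigned,
                  ggplot2::aes(x = .data$feature_class, y = .data$entropy)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "methylation entropy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a TSS methylation-entropy profile
#'
#' One line per expression quintile (5 = highest expressed) of mean
#' entropy (or level) against position relative to the TSS.
#'
#' @param object a `meth_tss_profile` from [tss_profile()].
#' @param metric `"entropy"` or `"level"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot meth_tss_profile
#' @export
autoplot.meth_tss_profile <- function(object, metric = c("entropy", "level"),
                                      ...) {
  metric <- match.arg(metric)
  ycol <- paste0("mean_", metric)
  window <- attr(object, "window") %||% 100
  df <- as_tibble(object)
  df$pos <- df$bin_start + window / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data[[ycol]],
                                   colour = factor(.data$quintile))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = paste("mean methylation", metric),
                  colour = "expression\nquintile") +
    ggplot2::theme_minimal()
}
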