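#' Dot plot of a per-sample metric by group
#'
#' The standard repertoire dot plot: one point per sample, grouped on the x
#' axis, with the group median marked by a crossbar.
#'
#' @param metrics Per-sample metric tibble ([summarize_repertoire()] rows).
#' @param design Tibble with `sample` and `group`.
#' @param metric Metric column to plot.
#' @return A ggplot object.
#' @export
plot_group_metric <- function(metrics, design, metric = "richness") {
  m <- dplyr::inner_join(metrics, design, by = "sample")
  ggplot2::ggplot(m, ggplot2::aes(
    x = .data$group, y = .data[[metric]]
  )) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(
      fun = stats::median, geom = "crossbar",
      width = 0.4, linewidth = 0.4, colour = "red"
    ) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}

#' Dot plot of RUNX1 hit distances to the deletion border by category
#'
#' @param records Spatial record tibble from [spatial_classify()].
#' @return A ggplot object.
#' @export
plot_spatial_distances <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$category, y = .data$distance_bp
  )) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(
      fun = stats::median, geom = "crossbar",
      width = 0.5, linewidth = 0.4, colour = "red"
    ) +
    ggplot2::labs(x = NULL, y = "distance to deletion border (bp)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an enrichment result
#'
#' Observed versus expected positive-unit counts with the fold and Z-score
#' annotated.
#'
#' @param object A `vdj_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vdj_enrichment
#' @export
autoplot.vdj_enrichment <- function(object, ...) {
  df <- tibble(
    what = factor(c("expected", "observed"), c("expected", "observed")),
    count = c(object$expected, object$observed)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$count)) +
    ggplot2::geom_col(width = 0.6, fill = c("grey70", "steelblue")) +
    ggplot2::labs(
      x = NULL, y = "positive units",
      subtitle = sprintf(
        "fold %.2f, Z %.2f, P %.3g", object$fold, object$z, object$p_binomial
      )
    ) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
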