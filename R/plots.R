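# ggplot2 summaries of the main result types, and a thin dendrogram plot.

#' Plot per-window Mendelian-error counts
#'
#' Bars of total errors per bin, with the error-prone threshold drawn.
#'
#' @param scan Result of [window_error_scan()].
#' @param min_total Threshold line (default 11).
#' @return A ggplot object.
#' @export
plot_window_errors <- function(scan, min_total = 11L) {
  totals <- dplyr::distinct(scan$window_table, .data$contig, .data$bin_start,
                            .data$total_errors)
  ggplot2::ggplot(totals,
                  ggplot2::aes(x = .data$bin_start / 1000,
                               y = .data$total_errors)) +
    ggplot2::geom_col(width = 8, fill = "grey40") +
    ggplot2::geom_hline(yintercept = min_total - 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "Mendelian errors / 10 kb bin") +
    ggplot2::theme_minimal()
}

#' Plot backbone coverage from a screen result
#' @param screen Result of [screen_backbone()] (carries the depth vector).
#' @return A ggplot object.
#' @export
plot_backbone_coverage <- function(screen) {
  depth <- attr(screen, "depth")
  d <- tibble::tibble(pos = seq_along(depth), depth = depth)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::labs(x = "backbone position (bp)", y = "depth",
                  subtitle = sprintf("breadth %.3f, present: %s",
                                     screen$breadth, screen$present)) +
    ggplot2::theme_minimal()
}

#' Boxplot of per-trio error rates by study group
#' @param x A `polled_anova` object from [oneway_anova()].
#' @param object,... Unused (autoplot protocol).
#' @return A ggplot object.
#' @method autoplot polled_anova
#' @export
autoplot.polled_anova <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::labs(x = NULL, y = "% Mendelian errors per variant",
                  subtitle = sprintf("F(%d, %d) = %.2f, p = %.3f",
                                     object$df_between, object$df_within,
                                     object$F, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot a dendrogram
#' @param tree An ape `phylo` from [build_dendrogram()].
#' @param type Plot type passed to [ape::plot.phylo()] (default "fan",
#'   as relatedness dendrograms are usually drawn).
#' @param ... Passed on to [ape::plot.phylo()].
#' @return Invisibly, the tree.
#' @export
plot_dendrogram <- function(tree, type = "fan", ...) {
  ape::plot.phylo(tree, type = type, ...)
  invisible(tree)
}
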