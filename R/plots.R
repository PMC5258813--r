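#' Bidimensional expression plot of a quadrant result
#'
#' One dot per cell on log-scaled marker axes, colored by quadrant in the
#' usual cytometry scheme (double-positive red, single-positives
#' yellow/green, double-negative black), with the two gate thresholds and
#' per-quadrant percentages annotated.
#'
#' @param x A [classify_quadrants()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_quadrants <- function(x, ...) {
  cx <- channel_column(x$cells, x$gate_x$channel)
  cy <- channel_column(x$cells, x$gate_y$channel)
  df <- dplyr::mutate(x$cells,
                      .x = pmax(.data[[cx]], 1), .y = pmax(.data[[cy]], 1))
  cols <- c(double_pos = "red3", x_single_pos = "gold2",
            y_single_pos = "green4", double_neg = "grey15")
  lab <- sprintf("%s %.1f%%", names(x$percentages), x$percentages)
  ggplot2::ggplot(df, ggplot2::aes(.data$.x, .data$.y,
                                   colour = .data$quadrant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = max(x$gate_x$threshold, 1),
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = max(x$gate_y$threshold, 1),
                        linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(x = paste(x$gate_x$channel, "mean intensity"),
                  y = paste(x$gate_y$channel, "mean intensity"),
                  subtitle = paste(lab, collapse = "   "),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quadrant_result <- function(object, ...) plot_quadrants(object, ...)

#' Expression histogram plot
#'
#' @param hist Tibble from [expression_histogram()].
#' @param ... Unused.
#' @return A ggplot with the negative partition in black and the positive
#'   partition in red.
#' @export
plot_expression_histogram <- function(hist, ...) {
  long <- tidyr::pivot_longer(hist, c("count_negative", "count_positive"),
                              names_to = "partition", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = sqrt(.data$lower * .data$upper),
                                     y = .data$n,
                                     fill = .data$partition)) +
    ggplot2::geom_col(width = 0.9, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(
      values = c(count_negative = "grey15", count_positive = "red3"),
      labels = c("negative", "positive")) +
    ggplot2::labs(x = "mean intensity", y = "cells", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Imaging-vs-flow concordance scatter
#'
#' @param profiles Tibble with `line`, `marker`, `imaging`, `flow` percent
#'   positives (as from [simulate_study()]).
#' @param ... Unused.
#' @return A ggplot, one panel per line, identity line dashed.
#' @export
plot_concordance <- function(profiles, ...) {
  ggplot2::ggplot(profiles, ggplot2::aes(.data$imaging, .data$flow,
                                         colour = .data$marker)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~line) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "imaging cytometry (% positive)",
                  y = "flow cytometry (% positive)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.concordance_result <- function(object, ...) {
  ggplot2::ggplot(object$lines,
                  ggplot2::aes(.data$line, .data$mean_r)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_r - .data$se_r,
                                        ymax = .data$mean_r + .data$se_r),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_replicates, y = 0.05),
                       colour = "white") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Pearson r (mean ± SE)") +
    ggplot2::theme_minimal()
}

#' Colony overlay of gated cells
#'
#' Plots cell centroids in image coordinates, colored by quadrant class,
#' with edge-band cells ringed — the backtracked view linking the
#' expression profile to colony geography.
#'
#' @param scored Cell table with `quadrant`, `colony_id` and `edge_flag`
#'   (from gating + [edge_scores()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_colony_overlay <- function(scored, ...) {
  cols <- c(double_pos = "red3", x_single_pos = "gold2",
            y_single_pos = "green4", double_neg = "grey15")
  ggplot2::ggplot(scored, ggplot2::aes(.data$col, .data$row,
                                       colour = .data$quadrant)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = dplyr::filter(scored,
                                             !is.na(.data$edge_flag) &
                                               .data$edge_flag),
                        shape = 1, size = 2.2, colour = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)", colour = NULL) +
    ggplot2::theme_minimal()
}
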