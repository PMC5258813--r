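## intensity column for a channel: `mean_<channel>` in imaging cell tables,
## the bare channel name in flow tables
channel_column <- function(tbl, channel) {
  col <- paste0("mean_", channel)
  if (col %in% names(tbl)) return(col)
  if (channel %in% names(tbl)) return(channel)
  abort(sprintf("channel '%s' not in table", channel))
}

#' Fit a positivity threshold from a negative control
#'
#' Thresholds are derived from a control sample assayed without primary
#' antibody: the gate is the empirical `q`-quantile (linear-interpolation
#' definition, `stats::quantile` type 7) of the control cells' mean
#' intensity on the channel. The default `q = 0.995` tolerates 0.5% false
#' positives on the control.
#'
#' @param control Cell table (tibble) of control cells.
#' @param channel Channel name; column `mean_<channel>` must exist.
#' @param q Quantile in `(0, 1]`.
#' @return A `gate_spec`: list with `channel`, `threshold`, `q`, `control_n`.
#' @export
fit_threshold <- function(control, channel, q = 0.995) {
  v <- control[[channel_column(control, channel)]]
  if (length(v) == 0) abort("empty control table")
  if (!(q > 0 && q <= 1)) abort("q must be in (0, 1]")
  structure(list(channel = channel,
                 threshold = quantile(v, q, names = FALSE, type = 7),
                 q = q, control_n = length(v)),
            class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("<gate_spec> %s > %.2f (q = %.3f from %d control cells)\n",
              x$channel, x$threshold, x$q, x$control_n))
  invisible(x)
}

cell_positive <- function(cells, gate) {
  cells[[channel_column(cells, gate$channel)]] > gate$threshold  # ties negative
}

#' Percent of cells positive for a marker
#'
#' `100 * #(mean intensity > threshold) / n`, strict inequality.
#'
#' @param cells Cell table.
#' @param gate A [fit_threshold()] gate.
#' @return Percentage in `[0, 100]`.
#' @export
percent_positive <- function(cells, gate) {
  if (nrow(cells) == 0) abort("empty cell table")
  100 * mean(cell_positive(cells, gate))
}

#' Quadrant classification on two gated channels
#'
#' Assigns every cell to exactly one quadrant of the bidimensional
#' expression plot (x marker vs y marker): `double_pos`, `x_single_pos`,
#' `y_single_pos` or `double_neg`, by strict comparison against each gate.
#'
#' @param cells Cell table.
#' @param gate_x,gate_y Gates for the two channels.
#' @return A `quadrant_result`: list with `cells` (input plus a `quadrant`
#'   column), `counts`, `percentages`, `total_n` and the two gates. Use
#'   [tidy()] / [glance()] for tabular summaries.
#' @export
classify_quadrants <- function(cells, gate_x, gate_y) {
  if (nrow(cells) == 0) abort("empty cell table")
  px <- cell_positive(cells, gate_x)
  py <- cell_positive(cells, gate_y)
  quadrant <- dplyr::case_when(px & py ~ "double_pos",
                               px & !py ~ "x_single_pos",
                               !px & py ~ "y_single_pos",
                               TRUE ~ "double_neg")
  counts <- vapply(phenotype_levels, function(k) sum(quadrant == k),
                   integer(1))
  structure(list(cells = dplyr::mutate(cells, quadrant = quadrant),
                 counts = counts,
                 percentages = 100 * counts / nrow(cells),
                 total_n = nrow(cells),
                 gate_x = gate_x, gate_y = gate_y),
            class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat("<quadrant_result>", x$total_n, "cells\n")
  for (k in names(x$counts))
    cat(sprintf("  %-13s %6d  %6.2f%%\n", k, x$counts[k], x$percentages[k]))
  invisible(x)
}

#' @export
tidy.quadrant_result <- function(x, ...) {
  tibble(quadrant = names(x$counts),
         count = as.integer(x$counts),
         percent = as.numeric(x$percentages))
}

#' @export
glance.quadrant_result <- function(x, ...) {
  tibble(total_n = x$total_n,
         pct_x_positive = as.numeric(x$percentages["double_pos"] +
                                       x$percentages["x_single_pos"]),
         pct_y_positive = as.numeric(x$percentages["double_pos"] +
                                       x$percentages["y_single_pos"]),
         threshold_x = x$gate_x$threshold,
         threshold_y = x$gate_y$threshold)
}

#' Log-binned expression histogram with positive/negative partition
#'
#' Bins the per-cell mean intensities of one channel into `n_bins`
#' log-spaced bins over `[1, ceiling]` (camera ceiling by default); values
#' below 1 fall in the first bin, values at the ceiling in the last. The
#' gate threshold partitions cells into negative (black) and positive (red)
#' as in a one-dimensional cytometry histogram.
#'
#' @param cells Cell table.
#' @param channel Channel name.
#' @param gate Gate for the channel.
#' @param n_bins Number of bins (> 0).
#' @param ceiling_val Upper edge of the binning range (default `4095`, the
#'   12-bit camera ceiling).
#' @return Tibble with `bin`, `lower`, `upper`, `count`, `count_positive`,
#'   `count_negative`; counts sum to `nrow(cells)`.
#' @export
expression_histogram <- function(cells, channel, gate, n_bins = 64,
                                 ceiling_val = 4095) {
  if (nrow(cells) == 0) abort("empty cell table")
  if (n_bins < 1) abort("n_bins must be positive")
  v <- pmin(pmax(cells[[channel_column(cells, channel)]], 1), ceiling_val)
  edges <- exp(seq(log(1), log(ceiling_val), length.out = n_bins + 1))
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pos <- cell_positive(cells, gate)
  tibble(bin = seq_len(n_bins),
         lower = edges[-length(edges)],
         upper = edges[-1],
         count = tabulate(idx, n_bins),
         count_positive = tabulate(idx[pos], n_bins),
         count_negative = tabulate(idx[!pos], n_bins))
}
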