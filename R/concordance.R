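#' Pearson correlation between two percent-positive profiles
#'
#' Standard product-moment correlation, with the domain checks that matter
#' for marker profiles: equal lengths of at least 3, and no constant vector
#' (for which r is undefined).
#'
#' @param x,y Numeric vectors (percent-positive per marker).
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("profiles have different lengths")
  if (length(x) < 3) abort("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0)
    abort("correlation undefined for a constant profile")
  cor(x, y, method = "pearson")
}

#' Imaging-vs-flow concordance summary
#'
#' Correlates imaging-derived and flow-derived percent-positive marker
#' profiles within each replicate (one r per replicate, computed across the
#' markers of the panel), then summarizes each line by the mean and standard
#' error of r over its replicates (`SE = sd / sqrt(n)`, sample sd; `SE = 0`
#' with an `n = 1` flag for a single replicate). Set `pool_replicates =
#' TRUE` to instead pool all marker-replicate points of a line into a
#' single correlation.
#'
#' @param profiles Tibble with columns `line`, `replicate`, `marker`,
#'   `imaging`, `flow` (percent positive in each modality).
#' @param pool_replicates Pool markers and replicates jointly per line
#'   (non-default alternative reading).
#' @return A `concordance_result` with per-replicate r (`replicates`) and
#'   per-line summaries (`lines`: `mean_r`, `se_r`, `n_replicates`,
#'   `single_replicate` flag).
#' @export
concordance_summary <- function(profiles, pool_replicates = FALSE) {
  need <- c("line", "replicate", "marker", "imaging", "flow")
  if (!all(need %in% names(profiles)))
    abort(paste("profiles must have columns:", paste(need, collapse = ", ")))
  chk <- profiles |>
    dplyr::group_by(.data$line, .data$replicate) |>
    dplyr::summarise(markers = paste(sort(.data$marker), collapse = "|"),
                     .groups = "drop")
  if (length(unique(chk$markers)) > 1)
    abort("marker sets differ across replicates")

  if (pool_replicates) {
    lines <- profiles |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(mean_r = pearson_r(.data$imaging, .data$flow),
                       se_r = 0,
                       n_replicates = dplyr::n_distinct(.data$replicate),
                       .groups = "drop") |>
      dplyr::mutate(single_replicate = .data$n_replicates == 1)
    reps <- NULL
  } else {
    reps <- profiles |>
      dplyr::group_by(.data$line, .data$replicate) |>
      dplyr::summarise(r = pearson_r(.data$imaging, .data$flow),
                       n_markers = dplyr::n(), .groups = "drop")
    lines <- reps |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(mean_r = mean(.data$r),
                       sd_r = sd(.data$r),
                       n_replicates = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(se_r = ifelse(.data$n_replicates > 1,
                                  .data$sd_r / sqrt(.data$n_replicates), 0),
                    single_replicate = .data$n_replicates == 1) |>
      dplyr::select("line", "mean_r", "se_r", "n_replicates",
                    "single_replicate")
  }
  structure(list(replicates = reps, lines = lines,
                 pooled = pool_replicates),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>",
      if (x$pooled) "(pooled markers x replicates)\n" else "\n")
  print(as.data.frame(x$lines), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.concordance_result <- function(x, ...) {
  if (is.null(x$replicates)) x$lines else x$replicates
}

#' @export
glance.concordance_result <- function(x, ...) {
  tibble(n_lines = nrow(x$lines),
         min_line_mean_r = min(x$lines$mean_r),
         grand_mean_r = mean(x$lines$mean_r))
}
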