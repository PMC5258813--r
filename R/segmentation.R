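#' Nuclear segmentation parameters
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma, pixels.
#' @param background_percentile Percentile (0-100) of the image used as the
#'   global background estimate subtracted before thresholding.
#' @param min_nucleus_area,max_nucleus_area Retained object area bounds,
#'   square pixels.
#' @param min_foreground Minimum background-subtracted intensity (camera
#'   counts) for foreground; floors the Otsu threshold so pure read noise is
#'   never segmented.
#' @param split_h Seed-suppression depth for splitting touching nuclei, as a
#'   fraction of each object's maximum interior distance; `1` disables
#'   splitting (plain connected components).
#' @param border_policy `"keep"` (default) or `"discard"` objects touching
#'   the field border.
#' @return A validated `seg_params` list.
#' @export
seg_params <- function(smoothing_sigma = 1.5,
                       background_percentile = 5,
                       min_nucleus_area = 20,
                       max_nucleus_area = 2500,
                       min_foreground = 50,
                       split_h = 0.15,
                       border_policy = c("keep", "discard")) {
  border_policy <- match.arg(border_policy)
  if (!(min_nucleus_area > 0 && min_nucleus_area < max_nucleus_area))
    abort("need 0 < min_nucleus_area < max_nucleus_area")
  if (split_h < 0 || split_h > 1) abort("split_h must be in [0, 1]")
  if (background_percentile < 0 || background_percentile > 100)
    abort("background_percentile must be in [0, 100]")
  structure(list(smoothing_sigma = smoothing_sigma,
                 background_percentile = background_percentile,
                 min_nucleus_area = min_nucleus_area,
                 max_nucleus_area = max_nucleus_area,
                 min_foreground = min_foreground,
                 split_h = split_h,
                 border_policy = border_policy),
            class = "seg_params")
}

## 4-connected component labeling of a logical mask, optionally refined so
## components never cross different values of `within` (a label matrix).
## Returns an integer matrix with dense labels 1..K.
label_components4 <- function(mask, within = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) return(out)
  pos <- matrix(seq_len(nr * nc), nr, nc)
  grp <- if (is.null(within)) mask * 1L else within
  ## right-neighbour and down-neighbour edges between same-group fg pixels
  right_a <- pos[, -nc][mask[, -nc] & mask[, -1] & grp[, -nc] == grp[, -1]]
  right_b <- right_a + nr
  down_a <- pos[-nr, ][mask[-nr, ] & mask[-1, ] & grp[-nr, ] == grp[-1, ]]
  down_b <- down_a + 1L
  ## map pixel indices to vertex ids over fg pixels only
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  edges <- rbind(vid[c(right_a, down_a)], vid[c(right_b, down_b)])
  if (ncol(edges) > 0) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

#' Segment nuclei in the nuclear channel
#'
#' Reproduces an automated nuclear segmentation operation for fields of
#' tightly packed nuclei: Gaussian smoothing, global percentile background
#' subtraction, Otsu thresholding, hole filling, then a seeded watershed on
#' the Euclidean distance transform to split touching nuclei (seed
#' suppression depth `split_h` times each object's maximum interior
#' distance), followed by area filtering and the border policy. Output
#' labels are dense `1..K` and each label's pixel set is 4-connected.
#' Deterministic for fixed input.
#'
#' @param image Either an `image_field` (its `nuclear` channel is used) or a
#'   2-D numeric/integer matrix.
#' @param params A [seg_params()].
#' @return Integer label matrix; 0 is background.
#' @export
segment_nuclei <- function(image, params = seg_params()) {
  img <- if (inherits(image, "image_field")) image$channels$nuclear else image
  if (length(dim(img)) != 2) abort("nuclear image must be 2-D")
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (diff(range(img)) == 0) return(matrix(0L, nrow(img), ncol(img)))

  sm <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                 sigma = params$smoothing_sigma))
  bg <- quantile(sm, params$background_percentile / 100, names = FALSE)
  sm <- pmax(sm - bg, 0)
  if (max(sm) <= params$min_foreground)
    return(matrix(0L, nrow(img), ncol(img)))
  smn <- sm / max(sm)
  thr <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  mask <- sm > max(thr * max(sm), params$min_foreground)
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))

  ## split touching nuclei: per-object-normalized distance map + watershed
  cc <- label_components4(mask)
  if (params$split_h < 1) {
    dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
    obj_max <- tapply(dm[mask], cc[mask], max)
    dmn <- dm
    dmn[mask] <- dm[mask] / pmax(obj_max[as.character(cc[mask])], 1e-9)
    ws <- EBImage::watershed(EBImage::Image(dmn), tolerance = params$split_h,
                             ext = 1)
    labels <- label_components4(mask, within = as.matrix(ws))
  } else {
    labels <- cc
  }

  ## area filter
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= params$min_nucleus_area &
                  areas <= params$max_nucleus_area)
  labels[!(labels %in% keep)] <- 0L

  if (params$border_policy == "discard") {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    labels[labels %in% border[border > 0]] <- 0L
  }

  ## relabel dense 1..K
  u <- sort(unique(labels[labels > 0]))
  if (length(u) > 0) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  labels
}

#' Stitch a grid of image tiles into one field
#'
#' Abutting row-major mosaic with no overlap or blending, as produced by a
#' tiled whole-well acquisition: pixel `(r, c)` of tile `(i, j)` lands at
#' `(i * h + r, j * w + c)` (0-based).
#'
#' @param tiles List of 2-D matrices, all the same shape, row-major order.
#' @param grid Integer `(rows, cols)` of the tile grid.
#' @return Matrix of shape `(rows * h, cols * w)`.
#' @export
stitch_tiles <- function(tiles, grid) {
  grid <- as.integer(grid)
  if (length(tiles) != prod(grid))
    abort(sprintf("expected %d tiles for a %dx%d grid, got %d",
                  prod(grid), grid[1], grid[2], length(tiles)))
  shapes <- vapply(tiles, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    abort("all tiles must share the same shape")
  h <- shapes[1, 1]; w <- shapes[2, 1]
  out <- matrix(vector(mode = typeof(tiles[[1]]), 1), grid[1] * h, grid[2] * w)
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
    out[(i - 1) * h + seq_len(h), (j - 1) * w + seq_len(w)] <-
      tiles[[(i - 1) * grid[2] + j]]
  }
  out
}

#' Match segmented centroids against ground truth
#'
#' Greedy nearest-pair matching between segmented and true centroids within
#' a match radius; used to score segmentation recovery (precision, recall,
#' F1) against the simulator's ground truth.
#'
#' @param cells Cell table with `row`, `col` centroids (e.g. from
#'   [measure_cells()]).
#' @param truth Ground-truth tibble with `row`, `col`.
#' @param match_radius Maximum centroid distance for a match, pixels.
#' @return One-row tibble: `n_seg`, `n_true`, `n_matched`, `precision`,
#'   `recall`, `f1`, `mean_match_dist`.
#' @export
match_centroids <- function(cells, truth, match_radius) {
  ns <- nrow(cells); nt <- nrow(truth)
  if (ns == 0 || nt == 0)
    return(tibble(n_seg = ns, n_true = nt, n_matched = 0L,
                  precision = 0, recall = 0, f1 = 0,
                  mean_match_dist = NA_real_))
  d <- outer(cells$row, truth$row, `-`)^2 + outer(cells$col, truth$col, `-`)^2
  d <- sqrt(d)
  d[d > match_radius] <- Inf
  matched <- 0L; dists <- numeric(0)
  repeat {
    m <- which.min(d)
    if (!is.finite(d[m])) break
    ij <- arrayInd(m, dim(d))
    matched <- matched + 1L
    dists <- c(dists, d[m])
    d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
  }
  precision <- matched / ns; recall <- matched / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(n_seg = ns, n_true = nt, n_matched = matched,
         precision = precision, recall = recall, f1 = f1,
         mean_match_dist = if (matched > 0) mean(dists) else NA_real_)
}
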