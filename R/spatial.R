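#' Group cells into colonies by single-linkage clustering of centroids
#'
#' Colonies are the connected components of the graph linking any two cells
#' whose centroids lie within `linkage_distance` (single linkage).
#' Components smaller than `min_colony_size` are treated as delaminated
#' (colony id 0). Each colony's footprint is the union of its members'
#' nucleus discs dilated by `dilate_radius`, holes filled.
#'
#' @param cells Cell table with `row`, `col` centroids; an optional
#'   `nucleus_radius` column sets per-cell disc radii (else
#'   `sqrt(area / pi)` or `default_radius`).
#' @param linkage_distance Linkage distance, pixels (> 0). Default of
#'   3x the median nucleus diameter when `NULL`.
#' @param min_colony_size Minimum member count for a real colony.
#' @param field_shape `(rows, cols)` of the field the footprints live in;
#'   required for footprint rendering.
#' @param dilate_radius Footprint dilation radius, pixels (default: the
#'   median nucleus diameter).
#' @param default_radius Fallback nucleus radius, pixels.
#' @return A `colony_assignment`: list with `cells` (input plus
#'   `colony_id`), `colonies` (tibble `colony_id`, `n_cells`), and
#'   `footprints` (integer matrix, 0 = background, else colony id), plus the
#'   parameters used.
#' @export
assign_colonies <- function(cells, linkage_distance = NULL,
                            min_colony_size = 10, field_shape = NULL,
                            dilate_radius = NULL, default_radius = 5) {
  if (nrow(cells) < 1) abort("need at least one cell")
  radii <- if ("nucleus_radius" %in% names(cells)) cells$nucleus_radius
  else if ("area" %in% names(cells)) sqrt(cells$area / pi)
  else rep(default_radius, nrow(cells))
  med_diam <- 2 * stats::median(radii)
  if (is.null(linkage_distance)) linkage_distance <- 3 * med_diam
  if (linkage_distance <= 0) abort("linkage distance must be positive")
  if (is.null(dilate_radius)) dilate_radius <- med_diam

  ## single-linkage components at the linkage distance
  n <- nrow(cells)
  if (n == 1) {
    comp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(cbind(cells$row, cells$col)),
                        method = "single")
    comp <- stats::cutree(hc, h = linkage_distance)
  }
  sizes <- tabulate(comp)
  real <- which(sizes >= min_colony_size)
  ## relabel: colonies ordered by first-appearing member, small ones -> 0
  colony_id <- integer(n)
  nxt <- 0L
  for (j in seq_len(n)) {
    if (colony_id[j] == 0L && comp[j] %in% real) {
      nxt <- nxt + 1L
      colony_id[comp == comp[j]] <- nxt
    }
  }

  footprints <- NULL
  if (!is.null(field_shape)) {
    footprints <- matrix(0L, field_shape[1], field_shape[2])
    for (k in seq_len(nxt)) {
      m <- matrix(0, field_shape[1], field_shape[2])
      idx <- which(colony_id == k)
      for (j in idx) {
        rad <- radii[j] + dilate_radius
        ri <- max(1, floor(cells$row[j] - rad + 1)):
          min(field_shape[1], ceiling(cells$row[j] + rad + 1))
        ci <- max(1, floor(cells$col[j] - rad + 1)):
          min(field_shape[2], ceiling(cells$col[j] + rad + 1))
        d2 <- outer((ri - 1 - cells$row[j])^2, (ci - 1 - cells$col[j])^2, `+`)
        m[ri, ci] <- pmax(m[ri, ci], (d2 <= rad^2) * 1)
      }
      m <- as.matrix(EBImage::fillHull(EBImage::Image(m)))
      footprints[m > 0 & footprints == 0L] <- k
    }
  }
  colony_sizes <- tabulate(colony_id, nxt)
  cells$colony_id <- colony_id
  structure(list(cells = cells,
                 colonies = tibble(colony_id = seq_len(nxt),
                                   n_cells = colony_sizes),
                 footprints = footprints,
                 linkage_distance = linkage_distance,
                 min_colony_size = min_colony_size,
                 dilate_radius = dilate_radius,
                 median_nucleus_diameter = med_diam),
            class = "colony_assignment")
}

#' @export
print.colony_assignment <- function(x, ...) {
  cat("<colony_assignment>", nrow(x$colonies), "colonies,",
      sum(x$cells$colony_id > 0), "of", nrow(x$cells),
      "cells assigned (linkage", round(x$linkage_distance, 1), "px)\n")
  invisible(x)
}

#' Distance-to-boundary scores for in-colony cells
#'
#' For every assigned cell, `boundary_distance` is the Euclidean distance
#' transform of its colony footprint evaluated at the cell centroid, minus
#' the footprint's dilation margin (so it approximates distance to the
#' colony boundary itself, floored at 0);
#' `normalized_score` rescales it by the colony's maximum interior distance
#' (0 = on the boundary, 1 = deepest interior point; defined as 0 for
#' single-cell colonies); `edge_flag` marks cells within `edge_band` pixels
#' of the boundary. Delaminated cells carry `NA` scores. A centroid falling
#' outside its colony footprint is clamped to distance 0 with a warning.
#'
#' @param assignment A [assign_colonies()] result with footprints.
#' @param edge_band Edge band width in pixels; default 1.5x the median
#'   nucleus diameter.
#' @return The assignment's cell table plus `boundary_distance`,
#'   `normalized_score`, `edge_flag`.
#' @export
edge_scores <- function(assignment, edge_band = NULL) {
  if (is.null(assignment$footprints))
    abort("assignment has no footprints; call assign_colonies() with field_shape")
  if (is.null(edge_band))
    edge_band <- 1.5 * assignment$median_nucleus_diameter
  fp <- assignment$footprints
  dil <- assignment$dilate_radius %||% 0
  dm <- as.matrix(EBImage::distmap(EBImage::Image((fp > 0) * 1)))
  dm <- pmax(dm - dil, 0)
  cells <- assignment$cells
  n <- nrow(cells)
  bd <- rep(NA_real_, n); ns <- rep(NA_real_, n); ef <- rep(NA, n)
  ## per-colony max interior distance
  cmax <- vapply(seq_len(nrow(assignment$colonies)), function(k) {
    v <- dm[fp == k]
    if (length(v) == 0) 0 else max(v)
  }, numeric(1))
  clamped <- 0L
  for (j in seq_len(n)) {
    k <- cells$colony_id[j]
    if (k == 0) next
    r <- round(cells$row[j]) + 1L; c <- round(cells$col[j]) + 1L
    r <- min(max(r, 1L), nrow(fp)); c <- min(max(c, 1L), ncol(fp))
    if (fp[r, c] != k) { bd[j] <- 0; clamped <- clamped + 1L }
    else bd[j] <- dm[r, c]
    ns[j] <- if (assignment$colonies$n_cells[k] <= 1 || cmax[k] == 0) 0
    else min(1, bd[j] / cmax[k])
    ef[j] <- bd[j] <= edge_band
  }
  if (clamped > 0)
    warn(sprintf("%d cell centroid(s) outside their colony footprint; boundary distance clamped to 0", clamped))
  cells$boundary_distance <- bd
  cells$normalized_score <- ns
  cells$edge_flag <- ef
  cells
}

#' Edge enrichment of a marker phenotype, with permutation test
#'
#' Tests whether a phenotype concentrates at colony peripheries. The
#' statistic is `E = (edge fraction among phenotype cells) - (edge fraction
#' among all in-colony cells)`, computed over in-colony cells only. The
#' two-sided p-value comes from a permutation null that shuffles the
#' phenotype labels over cells (preserving the spatial autocorrelation of
#' the edge flags), with the add-one correction `p = (b + 1) / (n + 1)`.
#'
#' @param cells Cell table with `quadrant` (or `phenotype`), `colony_id` and
#'   `edge_flag` columns (from gating + [edge_scores()]).
#' @param phenotype Phenotype class to test.
#' @param n_permutations Number of label permutations (default 1999).
#' @param seed Seed for the permutations.
#' @return An `edge_enrichment`: list with `statistic` (E), `p_value`,
#'   `n_phenotype`, `n_cells`, `edge_fraction_phenotype`,
#'   `edge_fraction_all`, `n_permutations`.
#' @export
phenotype_edge_enrichment <- function(cells, phenotype,
                                      n_permutations = 1999, seed = 1L) {
  lab_col <- if ("quadrant" %in% names(cells)) "quadrant"
  else if ("phenotype" %in% names(cells)) "phenotype"
  else abort("cells need a quadrant or phenotype column")
  incol <- cells[cells$colony_id > 0, ]
  if (nrow(incol) < 10) abort("need at least 10 in-colony cells")
  if (any(is.na(incol$edge_flag))) abort("in-colony cells must carry edge flags")
  is_ph <- incol[[lab_col]] == phenotype
  if (!any(is_ph)) abort(sprintf("phenotype '%s' absent among in-colony cells", phenotype))
  edge <- incol$edge_flag
  stat <- function(ph) mean(edge[ph]) - mean(edge)
  e_obs <- stat(is_ph)
  set.seed(seed)
  n <- length(is_ph)
  perm <- vapply(seq_len(n_permutations),
                 function(i) stat(sample(is_ph, n)), numeric(1))
  b <- sum(abs(perm) >= abs(e_obs) - 1e-12)
  structure(list(statistic = e_obs,
                 p_value = (b + 1) / (n_permutations + 1),
                 n_phenotype = sum(is_ph), n_cells = n,
                 edge_fraction_phenotype = mean(edge[is_ph]),
                 edge_fraction_all = mean(edge),
                 phenotype = phenotype,
                 n_permutations = n_permutations),
            class = "edge_enrichment")
}

#' @export
print.edge_enrichment <- function(x, ...) {
  cat(sprintf("<edge_enrichment> %s: E = %.3f (edge %0.1f%% vs %0.1f%% overall), p = %.4f [%d cells, %d permutations]\n",
              x$phenotype, x$statistic, 100 * x$edge_fraction_phenotype,
              100 * x$edge_fraction_all, x$p_value, x$n_cells,
              x$n_permutations))
  invisible(x)
}

#' @export
tidy.edge_enrichment <- function(x, ...) {
  tibble(phenotype = x$phenotype, statistic = x$statistic,
         p_value = x$p_value, n_phenotype = x$n_phenotype,
         n_cells = x$n_cells,
         edge_fraction_phenotype = x$edge_fraction_phenotype,
         edge_fraction_all = x$edge_fraction_all)
}

#' Backtrack cells from the expression profile to the image
#'
#' Recovers, for each requested cell, the padded bounding-box crop of every
#' channel plus the nucleus outline — the profile-point-to-image navigation
#' that distinguishes imaging cytometry from flow.
#'
#' @param cell_ids Cell ids to backtrack.
#' @param cells Cell table with bounding boxes (from [measure_cells()]).
#' @param image An `image_field` or named list of channel matrices.
#' @param labels Label matrix the cells were measured from.
#' @param pad Padding around the bounding box, pixels.
#' @return Named list (one element per id): `cell` (the table row), `crops`
#'   (named list of channel crops), `label_crop`, `outline` (tibble of
#'   0-based boundary pixel coordinates relative to the field), and
#'   `origin` (0-based `(row, col)` of the crop's top-left corner).
#' @export
backtrack <- function(cell_ids, cells, image, labels, pad = 5L) {
  channels <- if (inherits(image, "image_field")) image$channels else image
  missing_ids <- setdiff(cell_ids, cells$cell_id)
  if (length(missing_ids) > 0)
    abort(paste("unknown cell ids:", paste(missing_ids, collapse = ", ")))
  nr <- nrow(labels); nc <- ncol(labels)
  out <- lapply(cell_ids, function(id) {
    rec <- cells[cells$cell_id == id, ]
    r0 <- max(0L, rec$bbox_r0 - pad); c0 <- max(0L, rec$bbox_c0 - pad)
    r1 <- min(nr, rec$bbox_r1 + pad); c1 <- min(nc, rec$bbox_c1 + pad)
    ri <- (r0 + 1L):r1; ci <- (c0 + 1L):c1
    lab_crop <- labels[ri, ci, drop = FALSE]
    inside <- lab_crop == id
    ## outline: nucleus pixels with a non-nucleus 4-neighbour
    er <- rbind(FALSE, inside[-nrow(inside), , drop = FALSE])
    wr <- rbind(inside[-1, , drop = FALSE], FALSE)
    ec <- cbind(FALSE, inside[, -ncol(inside), drop = FALSE])
    wc <- cbind(inside[, -1, drop = FALSE], FALSE)
    edge <- inside & !(er & wr & ec & wc)
    ow <- which(edge, arr.ind = TRUE)
    list(cell = rec,
         crops = lapply(channels, function(ch) ch[ri, ci, drop = FALSE]),
         label_crop = lab_crop,
         outline = tibble(row = ow[, 1] - 1L + r0, col = ow[, 2] - 1L + c0),
         origin = c(row = r0, col = c0))
  })
  names(out) <- as.character(cell_ids)
  out
}
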