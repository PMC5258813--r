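cells_at <- function(rows, cols, radius = 4) {
  tibble::tibble(cell_id = seq_along(rows), row = rows, col = cols,
                 nucleus_radius = radius)
}

test_that("single-linkage colony grouping matches intuition on toy clusters", {
  tight <- cells_at(c(10, 14, 18, 12, 16, 20, 11, 15, 19, 13),
                    c(10, 12, 10, 16, 18, 14, 21, 23, 22, 26))
  a <- assign_colonies(tight, linkage_distance = 8, min_colony_size = 5)
  expect_equal(nrow(a$colonies), 1)
  expect_true(all(a$cells$colony_id == 1))
  two <- cells_at(c(rep(10, 6), rep(80, 6)) + rep(c(0, 3, 6, 0, 3, 6), 2),
                  c(rep(10, 6), rep(80, 6)) + rep(c(0, 0, 0, 4, 4, 4), 2))
  b <- assign_colonies(two, linkage_distance = 8, min_colony_size = 3)
  expect_equal(nrow(b$colonies), 2)
  expect_equal(b$colonies$n_cells, c(6L, 6L))
  expect_error(assign_colonies(tight, linkage_distance = -1), "positive")
})

test_that("colony components equal the union-find single-linkage oracle", {
  set.seed(19)
  for (rep in 1:4) {
    n <- sample(30:50, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    linkage <- runif(1, 8, 18)
    a <- assign_colonies(cells_at(pts[, 1], pts[, 2]),
                         linkage_distance = linkage, min_colony_size = 1)
    oracle <- union_find_components(pts, linkage)
    ## identical partitions up to relabeling
    tab <- table(a$cells$colony_id, oracle)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

disc_assignment <- function(R = 30, extra_cells = NULL) {
  ## hand-built colony assignment: a perfect disc footprint of radius R
  ## centred at (R, R) on a (2R+1)^2 field
  cells <- dplyr::bind_rows(cells_at(R, R), extra_cells)
  cells$cell_id <- seq_len(nrow(cells))
  fp <- matrix(0L, 2 * R + 21, 2 * R + 21)
  for (r in seq_len(nrow(fp))) for (c in seq_len(ncol(fp)))
    if ((r - 1 - R - 10)^2 + (c - 1 - R - 10)^2 <= R^2) fp[r, c] <- 1L
  cells$row <- cells$row + 10; cells$col <- cells$col + 10
  structure(list(cells = dplyr::mutate(cells, colony_id = 1L),
                 colonies = tibble::tibble(colony_id = 1L,
                                           n_cells = nrow(cells)),
                 footprints = fp, linkage_distance = 30,
                 min_colony_size = 1, median_nucleus_diameter = 8),
            class = "colony_assignment")
}

test_that("a cell at the centre of a disc colony scores the full radius", {
  R <- 30
  ring <- cells_at(rep(R, 4), R + c(-24, -12, 12, 24))
  asn <- disc_assignment(R, ring)
  sc <- edge_scores(asn, edge_band = 7)
  centre <- sc[sc$row == R + 10 & sc$col == R + 10, ]
  expect_equal(centre$boundary_distance, R, tolerance = 0.06 * R)
  expect_equal(centre$normalized_score, 1, tolerance = 0.02)
  expect_false(centre$edge_flag)
  ## scores weakly decrease along a ray from centre to boundary
  ray <- sc[order(abs(sc$col - (R + 10))), ]
  expect_true(all(diff(ray$boundary_distance) <= 1e-9))
  expect_true(sc$edge_flag[sc$col == R + 10 - 24][1])
})

test_that("single-cell colonies take normalized score 0 by convention", {
  asn <- disc_assignment(12)
  sc <- edge_scores(asn)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$normalized_score, 0)
  expect_gt(sc$boundary_distance, 0)
})

test_that("centroids outside their footprint are clamped with a warning", {
  asn <- disc_assignment(12)
  asn$cells <- dplyr::bind_rows(
    asn$cells,
    dplyr::mutate(cells_at(1, 1), cell_id = 2L, colony_id = 1L))
  asn$colonies$n_cells <- 2L
  expect_warning(sc <- edge_scores(asn), "clamped")
  expect_equal(sc$boundary_distance[2], 0)
})

test_that("edge enrichment statistic matches direct counting", {
  ## 40 in-colony cells, 10 flagged edge; exactly those 10 carry the label
  cells <- tibble::tibble(cell_id = 1:40, colony_id = 1L,
                          edge_flag = c(rep(TRUE, 10), rep(FALSE, 30)),
                          quadrant = c(rep("y_single_pos", 10),
                                       rep("double_pos", 30)))
  e <- phenotype_edge_enrichment(cells, "y_single_pos", n_permutations = 99)
  expect_equal(e$statistic, 1 - 0.25)
  expect_lt(e$p_value, 0.05)
  ## all cells share the phenotype -> E = 0 exactly
  all_same <- dplyr::mutate(cells, quadrant = "double_pos")
  e0 <- phenotype_edge_enrichment(all_same, "double_pos", n_permutations = 99)
  expect_identical(e0$statistic, 0)
  expect_error(phenotype_edge_enrichment(cells, "absent_class"), "absent")
})

test_that("permutation p-values are reproducible and well-calibrated in shape", {
  set.seed(23)
  cells <- tibble::tibble(cell_id = 1:60, colony_id = 1L,
                          edge_flag = sample(c(TRUE, FALSE), 60, TRUE),
                          quadrant = sample(c("a", "b"), 60, TRUE))
  e1 <- phenotype_edge_enrichment(cells, "a", n_permutations = 499, seed = 7)
  e2 <- phenotype_edge_enrichment(cells, "a", n_permutations = 499, seed = 7)
  expect_identical(e1$p_value, e2$p_value)
  expect_gt(e1$p_value, 0)
  expect_lte(e1$p_value, 1)
  ## with the +1 correction, p can never be smaller than 1/(n+1)
  expect_gte(e1$p_value, 1 / 500)
})

test_that("backtracking returns crops that reproduce the stored quadrant class", {
  cfg <- tiny_config(seed = 55)
  sim <- generate_colony_field(cfg)
  an <- analyze_field(sim$field)
  ctl <- generate_colony_field(control_config(cfg))
  ctl_cells <- analyze_field(ctl$field)$cells
  gx <- fit_threshold(ctl_cells, "x"); gy <- fit_threshold(ctl_cells, "y")
  qr <- classify_quadrants(an$cells, gx, gy)
  ids <- qr$cells$cell_id[c(1, 5, 9)]
  bt <- backtrack(ids, qr$cells, sim$field, an$labels, pad = 4)
  for (id in as.character(ids)) {
    b <- bt[[id]]
    ## crop contains the centroid
    expect_gte(b$cell$row, b$origin["row"])
    expect_lt(b$cell$row, b$origin["row"] + nrow(b$label_crop))
    ## recompute the quadrant from the crop's masked means
    mask <- b$label_crop == b$cell$cell_id
    mx <- mean(b$crops$x[mask]); my <- mean(b$crops$y[mask])
    requad <- if (mx > gx$threshold && my > gy$threshold) "double_pos"
    else if (mx > gx$threshold) "x_single_pos"
    else if (my > gy$threshold) "y_single_pos" else "double_neg"
    expect_identical(requad, b$cell$quadrant)
  }
  ## pad = 0 gives exactly the bounding box
  b0 <- backtrack(ids[1], qr$cells, sim$field, an$labels, pad = 0)[[1]]
  expect_equal(nrow(b0$label_crop), b0$cell$bbox_r1 - b0$cell$bbox_r0)
  expect_equal(ncol(b0$label_crop), b0$cell$bbox_c1 - b0$cell$bbox_c0)
  expect_error(backtrack(c(99999), qr$cells, sim$field, an$labels),
               "unknown")
})
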