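#' Quadrant fractions from two marker marginals
#'
#' Builds the four-quadrant phenotype mixture (`double_pos`, `x_single_pos`,
#' `y_single_pos`, `double_neg`) whose marginal positive fractions on the x
#' and y channels equal `p_x` and `p_y`. The joint is set by the assumed
#' association between the two markers: `"positive"` (maximal overlap, the
#' usual case for two pluripotency markers), `"negative"` (minimal overlap,
#' e.g. a pluripotency marker against an early-differentiation marker), or
#' `"independent"`.
#'
#' @param p_x,p_y Marginal positive fractions in `[0, 1]`.
#' @param association Joint structure; see Description.
#' @return Named numeric vector of four phenotype probabilities summing to 1.
#' @examples
#' quadrant_fractions(0.852, 0.302, "negative")
#' @export
quadrant_fractions <- function(p_x, p_y,
                               association = c("positive", "negative",
                                               "independent")) {
  association <- match.arg(association)
  stopifnot(is.numeric(p_x), is.numeric(p_y), length(p_x) == 1,
            length(p_y) == 1, p_x >= 0, p_x <= 1, p_y >= 0, p_y <= 1)
  dp <- switch(association,
               positive    = min(p_x, p_y),
               negative    = max(0, p_x + p_y - 1),
               independent = p_x * p_y)
  f <- c(double_pos   = dp,
         x_single_pos = p_x - dp,
         y_single_pos = p_y - dp,
         double_neg   = 1 - p_x - p_y + dp)
  f <- pmax(f, 0)
  f / sum(f)
}

phenotype_levels <- c("double_pos", "x_single_pos", "y_single_pos",
                      "double_neg")

## x-positivity / y-positivity status implied by each phenotype class
phenotype_status <- function(phenotype, channel) {
  if (channel == "x") phenotype %in% c("double_pos", "x_single_pos")
  else                phenotype %in% c("double_pos", "y_single_pos")
}

#' Default per-phenotype expression distributions
#'
#' Lognormal location/scale (in arbitrary pre-instrument fluorescence units)
#' for each (phenotype, channel) pair, derived from a marker-level
#' positive/negative pair of distributions. Positive cells express around
#' `positive_median` counts with `positive_sdlog` spread; negative cells sit
#' near the autofluorescence floor.
#'
#' @param positive_median,positive_sdlog Lognormal median / sdlog for a
#'   positive cell on a marker channel.
#' @param negative_median,negative_sdlog Same for a negative cell.
#' @return Tibble with columns `phenotype`, `channel`, `meanlog`, `sdlog`.
#' @export
default_expression_params <- function(positive_median = 600,
                                      positive_sdlog = 0.4,
                                      negative_median = 30,
                                      negative_sdlog = 0.5) {
  grid <- tidyr::expand_grid(phenotype = phenotype_levels,
                             channel = c("x", "y"))
  pos <- mapply(phenotype_status, grid$phenotype, grid$channel)
  tibble(phenotype = grid$phenotype,
         channel = grid$channel,
         meanlog = ifelse(pos, log(positive_median), log(negative_median)),
         sdlog = ifelse(pos, positive_sdlog, negative_sdlog))
}

#' Simulation configuration for synthetic colony fields
#'
#' Describes one synthetic field of flat, tightly packed stem-cell colonies
#' imaged in three channels (nuclear dye, a nuclear transcription-factor
#' marker on channel `x`, a surface marker on channel `y`), plus the
#' measurement contracts of both instruments: a camera quantized to
#' `2^camera_bit_depth` levels (4096 at the 12-bit default) and a flow
#' cytometer spanning `flow_decades` log decades (ceiling 10,000 at the
#' default 4).
#'
#' @param field_shape Integer `(rows, cols)` of the field in pixels.
#' @param n_colonies Number of colonies to place.
#' @param colony_radius_range Min/max mean colony radius, pixels.
#' @param colony_irregularity Amplitude of the low-order Fourier boundary
#'   perturbation (total amplitude capped at 0.3).
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius distribution,
#'   pixels.
#' @param packing_min_spacing Minimum centre-to-centre spacing between
#'   nuclei, as a fraction of the mean nucleus diameter.
#' @param nucleus_density Target nuclei per square pixel of colony footprint.
#' @param n_delaminated Count of delaminated cells placed outside colonies.
#' @param phenotype_fractions Named 4-vector over
#'   `double_pos/x_single_pos/y_single_pos/double_neg`; must sum to 1.
#' @param edge_bias Strength (>= 0) of the concentration of differentiated
#'   phenotypes toward the colony boundary; 0 = spatially uniform.
#' @param edge_phenotypes Phenotype classes treated as differentiated (the
#'   x-negative classes by default, since loss of the nuclear pluripotency
#'   factor marks differentiation).
#' @param expression_params Tibble as from [default_expression_params()].
#' @param nuclear_amplitude Median peak nuclear-dye intensity, camera counts.
#' @param background_level,background_noise_sd Camera background offset and
#'   read-noise sd, counts.
#' @param camera_bit_depth Camera bit depth (quantization ceiling
#'   `2^bits - 1`).
#' @param flow_decades Log decades of the flow cytometer display.
#' @param flow_cv Coefficient of variation of multiplicative flow
#'   measurement noise.
#' @param max_clip_fraction Maximum tolerated fraction of a colony footprint
#'   falling outside the field.
#' @param seed Integer seed; identical configuration implies bit-identical
#'   output.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(field_shape = c(660L, 660L),
                       n_colonies = 5L,
                       colony_radius_range = c(60, 95),
                       colony_irregularity = 0.12,
                       nucleus_radius_mean = 5,
                       nucleus_radius_sd = 0.6,
                       packing_min_spacing = 1.0,
                       nucleus_density = 0.0045,
                       n_delaminated = 15L,
                       phenotype_fractions =
                         quadrant_fractions(0.852, 0.302, "negative"),
                       edge_bias = 2,
                       edge_phenotypes = c("y_single_pos", "double_neg"),
                       expression_params = default_expression_params(),
                       nuclear_amplitude = 1500,
                       background_level = 100,
                       background_noise_sd = 5,
                       camera_bit_depth = 12L,
                       flow_decades = 4L,
                       flow_cv = 0.2,
                       max_clip_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(field_shape = as.integer(field_shape),
              n_colonies = as.integer(n_colonies),
              colony_radius_range = as.numeric(colony_radius_range),
              colony_irregularity = colony_irregularity,
              nucleus_radius_mean = nucleus_radius_mean,
              nucleus_radius_sd = nucleus_radius_sd,
              packing_min_spacing = packing_min_spacing,
              nucleus_density = nucleus_density,
              n_delaminated = as.integer(n_delaminated),
              phenotype_fractions = phenotype_fractions,
              edge_bias = edge_bias,
              edge_phenotypes = edge_phenotypes,
              expression_params = expression_params,
              nuclear_amplitude = nuclear_amplitude,
              background_level = background_level,
              background_noise_sd = background_noise_sd,
              camera_bit_depth = as.integer(camera_bit_depth),
              flow_decades = as.integer(flow_decades),
              flow_cv = flow_cv,
              max_clip_fraction = max_clip_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$field_shape) != 2 || any(cfg$field_shape < 1))
    abort("field_shape must be two positive integers (zero-area field)")
  if (cfg$n_colonies < 0) abort("n_colonies must be >= 0")
  f <- cfg$phenotype_fractions
  if (!all(phenotype_levels %in% names(f)))
    abort("phenotype_fractions must name all four quadrant classes")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    abort("phenotype_fractions must be >= 0 and sum to 1")
  if (cfg$edge_bias < 0) abort("edge_bias must be >= 0")
  if (cfg$packing_min_spacing <= 0) abort("packing_min_spacing must be > 0")
  if (cfg$camera_bit_depth < 1) abort("camera_bit_depth must be >= 1")
  if (cfg$flow_cv < 0) abort("flow_cv must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> field", paste(x$field_shape, collapse = "x"),
      "px,", x$n_colonies, "colonies, seed", x$seed, "\n")
  cat("  camera ceiling:", 2^x$camera_bit_depth - 1,
      " flow ceiling:", 10^x$flow_decades, "\n")
  cat("  phenotype fractions:",
      paste(sprintf("%s=%.3f", names(x$phenotype_fractions),
                    x$phenotype_fractions), collapse = " "), "\n")
  invisible(x)
}

## Star-convex colony boundary radius r(theta) = R (1 + sum a_k cos(k theta + phi_k))
blob_radius <- function(theta, blob) {
  pert <- rep(0, length(theta))
  for (i in seq_along(blob$k))
    pert <- pert + blob$a[i] * cos(blob$k[i] * theta + blob$phi[i])
  blob$R * (1 + pert)
}

draw_blob <- function(R, irregularity) {
  k <- 2:4
  a <- runif(3, 0, irregularity / k)
  tot <- sum(a)
  if (tot > 0.3) a <- a * 0.3 / tot
  list(R = R, k = k, a = a, phi = runif(3, 0, 2 * pi))
}

## Rejection-sample `target` points uniformly inside the blob (centred at
## cr, cc) while keeping every pair at least `spacing` apart, also against
## the already-placed points in `existing` (a 2-col matrix).
pack_nuclei <- function(cr, cc, blob, target, spacing, existing = NULL) {
  rmax <- blob$R * 1.3
  pts <- matrix(numeric(0), ncol = 2)
  sp2 <- spacing^2
  attempts <- 0L
  max_attempts <- max(2000L, 400L * target)
  while (nrow(pts) < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    dr <- runif(1, -rmax, rmax); dc <- runif(1, -rmax, rmax)
    rho <- sqrt(dr^2 + dc^2)
    if (rho > blob_radius(atan2(dc, dr), blob)) next
    cand <- c(cr + dr, cc + dc)
    if (nrow(pts) > 0 &&
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) < sp2) next
    if (!is.null(existing) && nrow(existing) > 0 &&
        min((existing[, 1] - cand[1])^2 + (existing[, 2] - cand[2])^2) < sp2)
      next
    pts <- rbind(pts, cand)
  }
  if (nrow(pts) < target)
    abort(sprintf(paste0("infeasible packing: placed %d of %d nuclei at ",
                         "minimum spacing %.2f px (packing_min_spacing / ",
                         "nucleus_density constraint)"),
                  nrow(pts), target, spacing))
  pts
}

## Render a channel as a sum of radially symmetric Gaussian-profile kernels
## (hard support at `support[j]` px around each centre), accumulated in
## place in a locally owned matrix.
render_channel <- function(nr, nc, rows, cols, sigmas, supports, peaks) {
  acc <- matrix(0, nr, nc)
  for (j in seq_along(rows)) {
    r0 <- rows[j]; c0 <- cols[j]; support <- supports[j]
    ri <- max(1L, floor(r0 - support)):min(nr, ceiling(r0 + support))
    ci <- max(1L, floor(c0 - support)):min(nc, ceiling(c0 + support))
    if (length(ri) == 0 || length(ci) == 0) next
    d2 <- outer((ri - 1 - r0)^2, (ci - 1 - c0)^2, `+`)
    k <- peaks[j] * exp(-d2 / (2 * sigmas[j]^2))
    k[d2 > support^2] <- 0
    acc[ri, ci] <- acc[ri, ci] + k
  }
  acc
}

quantize_channel <- function(m, bit_depth) {
  ceiling_val <- 2^bit_depth - 1
  m <- round(m)
  m[m < 0] <- 0
  m[m > ceiling_val] <- ceiling_val
  storage.mode(m) <- "integer"
  m
}

#' Generate a synthetic colony field with ground truth
#'
#' Renders one multi-channel field of flat colonies of tightly packed nuclei.
#' Colonies are smooth star-convex blobs; nuclei are placed by
#' minimum-spacing rejection sampling inside them (plus delaminated cells
#' outside); every cell carries a latent phenotype drawn from the configured
#' quadrant mixture, with differentiated classes concentrated toward the
#' colony boundary when `edge_bias > 0` (probability proportional to
#' `exp(-edge_bias * d)` in the normalized boundary distance `d`,
#' renormalized so the marginal mixture is preserved). The nuclear channel is
#' a sum of per-nucleus Gaussian-profile kernels; channel `x` (nuclear
#' marker) uses the same nuclear support scaled by the cell's true
#' expression; channel `y` (surface marker) covers the nucleus plus a small
#' annulus. All channels receive camera background plus Gaussian read noise
#' and are quantized to integer counts clipped at `2^bit_depth - 1`.
#'
#' Stochastic draws consume a single RNG seeded from `config$seed` in a
#' fixed order (colony radii, blob shapes, centres, nucleus positions and
#' radii, phenotypes, expressions, read noise), so identical configurations
#' give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param render Render the pixel channels (default). With `render = FALSE`
#'   only the ground truth is produced (image channels are `NULL`), which is
#'   much faster for studies that need latent states but no pixels; the
#'   ground truth is identical either way.
#' @return List with elements `field` (an `image_field`: named list of
#'   integer channel matrices `nuclear`, `x`, `y`, plus `bit_depth`) and
#'   `truth`, a tibble of per-cell ground truth: `cell_id` (dense 1..n),
#'   true centroid `row`/`col` (0-based pixel coordinates), `nucleus_radius`,
#'   `colony_id` (0 = delaminated), `phenotype`, `edge_dist_norm` (0 =
#'   boundary, 1 = deepest interior; `NA` for delaminated cells),
#'   `edge_dist_px`, and true expressions `expr_nuclear`, `expr_x`, `expr_y`.
#' @export
generate_colony_field <- function(config, render = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  nr <- config$field_shape[1]; nc <- config$field_shape[2]

  ## 1. colony geometry
  radii <- if (config$n_colonies > 0)
    runif(config$n_colonies, config$colony_radius_range[1],
          config$colony_radius_range[2]) else numeric(0)
  blobs <- lapply(radii, draw_blob, irregularity = config$colony_irregularity)
  ## sequential rejection placement; a bad early draw can dead-end, so the
  ## whole layout is retried from scratch a bounded number of times
  centers <- matrix(numeric(0), ncol = 2)
  for (restart in seq_len(30)) {
    centers <- matrix(numeric(0), ncol = 2)
    failed <- FALSE
    for (i in seq_len(config$n_colonies)) {
      rmax_i <- radii[i] * 1.3
      margin_r <- min(rmax_i, nr / 2); margin_c <- min(rmax_i, nc / 2)
      placed <- FALSE
      for (try in 1:2000) {
        cand <- c(runif(1, margin_r, nr - margin_r),
                  runif(1, margin_c, nc - margin_c))
        ok <- TRUE
        if (i > 1) {
          dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
          ok <- all(dd > (radii[seq_len(i - 1)] + radii[i]) * 1.05 + 5)
        }
        if (ok) { centers <- rbind(centers, cand); placed <- TRUE; break }
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) break
    if (restart == 30)
      abort("cannot place requested colonies without overlap; reduce n_colonies or colony_radius_range")
  }
  for (i in seq_len(config$n_colonies)) {
    ## clipped-footprint check
    th <- seq(0, 2 * pi, length.out = 90)
    br <- blob_radius(th, blobs[[i]])
    pr <- centers[i, 1] + br * cos(th); pc <- centers[i, 2] + br * sin(th)
    clip <- mean(pr < 0 | pr > nr - 1 | pc < 0 | pc > nc - 1)
    if (clip > config$max_clip_fraction)
      abort(sprintf("colony %d would clip %.0f%% of its boundary at the field border",
                    i, 100 * clip))
  }

  ## 2. nucleus placement
  spacing <- config$packing_min_spacing * 2 * config$nucleus_radius_mean
  rows <- numeric(0); cols <- numeric(0); colony_id <- integer(0)
  placed <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(config$n_colonies)) {
    target <- round(config$nucleus_density * pi * radii[i]^2)
    pts <- pack_nuclei(centers[i, 1], centers[i, 2], blobs[[i]], target,
                       spacing, existing = placed)
    placed <- rbind(placed, pts)
    rows <- c(rows, pts[, 1]); cols <- c(cols, pts[, 2])
    colony_id <- c(colony_id, rep.int(i, nrow(pts)))
  }
  ## delaminated cells: uniform over the field, outside every footprint
  n_del <- 0L
  if (config$n_delaminated > 0) {
    tries <- 0L
    while (n_del < config$n_delaminated && tries < 400L * config$n_delaminated) {
      tries <- tries + 1L
      cand <- c(runif(1, 2, nr - 3), runif(1, 2, nc - 3))
      inside <- FALSE
      for (i in seq_len(config$n_colonies)) {
        dr <- cand[1] - centers[i, 1]; dc <- cand[2] - centers[i, 2]
        if (sqrt(dr^2 + dc^2) <= blob_radius(atan2(dc, dr), blobs[[i]]) + spacing) {
          inside <- TRUE; break
        }
      }
      if (inside) next
      if (nrow(placed) > 0 &&
          min((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2) < spacing^2)
        next
      placed <- rbind(placed, cand)
      rows <- c(rows, cand[1]); cols <- c(cols, cand[2])
      colony_id <- c(colony_id, 0L)
      n_del <- n_del + 1L
    }
  }
  n <- length(rows)

  ## 3. nucleus radii
  nuc_r <- if (n > 0)
    pmin(pmax(rnorm(n, config$nucleus_radius_mean, config$nucleus_radius_sd),
              2), config$nucleus_radius_mean + 3 * config$nucleus_radius_sd)
  else numeric(0)

  ## 4. boundary distances (normalized; delaminated cells carry NA)
  edge_norm <- rep(NA_real_, n); edge_px <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    i <- colony_id[j]
    if (i == 0) next
    dr <- rows[j] - centers[i, 1]; dc <- cols[j] - centers[i, 2]
    rb <- blob_radius(atan2(dc, dr), blobs[[i]])
    edge_norm[j] <- max(0, 1 - sqrt(dr^2 + dc^2) / rb)
    edge_px[j] <- max(0, rb - sqrt(dr^2 + dc^2))
  }

  ## 5. phenotypes: differentiated classes biased toward the boundary,
  ##    marginals preserved by renormalizing the exp(-bias * d) weights
  f <- config$phenotype_fractions[phenotype_levels]
  diff_cls <- intersect(config$edge_phenotypes, phenotype_levels)
  p_diff <- sum(f[diff_cls])
  phen <- character(n)
  if (n > 0) {
    d_eff <- ifelse(is.na(edge_norm), 0, edge_norm)  # delaminated ~ boundary
    if (p_diff > 0 && p_diff < 1 && config$edge_bias > 0) {
      g <- exp(-config$edge_bias * d_eff)
      p_i <- pmin(1, p_diff * g / mean(g))
    } else p_i <- rep(p_diff, n)
    is_diff <- runif(n) < p_i
    f_diff <- f[diff_cls] / sum(f[diff_cls])
    und_cls <- setdiff(phenotype_levels, diff_cls)
    f_und <- f[und_cls] / sum(f[und_cls])
    u <- runif(n)
    pick <- function(u, probs, classes)
      classes[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
    if (any(is_diff)) phen[is_diff] <- pick(u[is_diff], f_diff, diff_cls)
    if (any(!is_diff)) phen[!is_diff] <- pick(u[!is_diff], f_und, und_cls)
  }

  ## 6. true expression (fixed draw order: nuclear, x, y)
  expr_nuc <- rlnorm(n, log(config$nuclear_amplitude), 0.15)
  ep <- config$expression_params
  expr_ch <- function(channel) {
    out <- numeric(n)
    for (ph in phenotype_levels) {
      row <- ep[ep$phenotype == ph & ep$channel == channel, ]
      idx <- which(phen == ph)
      if (length(idx) > 0)
        out[idx] <- rlnorm(length(idx), row$meanlog, row$sdlog)
    }
    out
  }
  expr_x <- expr_ch("x"); expr_y <- expr_ch("y")

  ## 7. render channels
  field <- NULL
  if (render) {
  nuclear <- render_channel(nr, nc, rows, cols, 0.45 * nuc_r, 2 * nuc_r,
                            expr_nuc)
  chx <- render_channel(nr, nc, rows, cols, 0.45 * nuc_r, 2 * nuc_r, expr_x)
  ## surface marker: nucleus + small annulus
  chy <- render_channel(nr, nc, rows, cols, 0.5 * nuc_r, 1.5 * nuc_r, expr_y)
  bg <- function() config$background_level +
    matrix(rnorm(nr * nc, 0, config$background_noise_sd), nr, nc)
  field <- list(
    nuclear = quantize_channel(nuclear + bg(), config$camera_bit_depth),
    x = quantize_channel(chx + bg(), config$camera_bit_depth),
    y = quantize_channel(chy + bg(), config$camera_bit_depth))
  field <- structure(list(channels = field,
                          bit_depth = config$camera_bit_depth),
                     class = "image_field")
  }

  truth <- tibble(cell_id = seq_len(n),
                  row = rows, col = cols,
                  nucleus_radius = nuc_r,
                  colony_id = colony_id,
                  phenotype = phen,
                  edge_dist_norm = edge_norm,
                  edge_dist_px = edge_px,
                  expr_nuclear = expr_nuc,
                  expr_x = expr_x,
                  expr_y = expr_y)
  list(field = field, truth = truth)
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<image_field>", d[1], "x", d[2], "px,",
      length(x$channels), "channels (", paste(names(x$channels),
                                              collapse = ", "),
      "),", x$bit_depth, "bit\n")
  invisible(x)
}

#' Simulate flow-cytometry readings of a dissociated population
#'
#' Emulates dissociating the imaged population into single-cell suspension
#' and measuring each cell's marker expression on a flow cytometer: the
#' measured intensity is the true expression times multiplicative lognormal
#' noise with coefficient of variation `config$flow_cv` (mean-preserving),
#' clipped to the instrument's dynamic range `[0, 10^flow_decades]`. Cell
#' order is randomized, as dissociation destroys spatial information.
#'
#' @param truth Ground-truth tibble from [generate_colony_field()].
#' @param config The [sim_config()] (supplies `flow_cv`, `flow_decades`).
#' @param seed Seed for measurement noise and shuffling; defaults to
#'   `config$seed` so a standalone call is reproducible.
#' @return Tibble with `cell_id` (originating cell) and measured `x`, `y`
#'   intensities in `[0, 10^flow_decades]`, in randomized order.
#' @export
simulate_flow_readings <- function(truth, config, seed = config$seed) {
  if (nrow(truth) == 0) abort("flow simulation requires a non-empty population")
  if (any(truth$expr_x < 0) || any(truth$expr_y < 0))
    abort("negative true expression: generator contract violation")
  if (!is.null(seed)) set.seed(seed)
  ceiling_val <- 10^config$flow_decades
  sdlog <- sqrt(log(1 + config$flow_cv^2))
  noisy <- function(v) {
    m <- if (sdlog > 0)
      v * rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog) else v
    pmin(pmax(m, 0), ceiling_val)
  }
  out <- tibble(cell_id = truth$cell_id,
                x = noisy(truth$expr_x),
                y = noisy(truth$expr_y))
  out[sample.int(nrow(out)), ]
}

#' Negative-control version of a configuration
#'
#' Returns the same imaging configuration with every cell forced to the
#' `double_neg` phenotype, emulating a control sample stained without
#' primary antibody: marker channels then carry only the background /
#' autofluorescence distribution, from which gate thresholds are fit.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the control field (defaults to `config$seed + 1000`
#'   so control and sample fields are independent draws).
#' @return A `sim_config` for the control field.
#' @export
control_config <- function(config, seed = config$seed + 1000L) {
  config$phenotype_fractions <- c(double_pos = 0, x_single_pos = 0,
                                  y_single_pos = 0, double_neg = 1)
  config$edge_bias <- 0
  config$seed <- as.integer(seed)
  config
}

#' Marker panel profiles for the four simulated hPSC lines
#'
#' Per-line marginal positive fractions for the five-marker panel
#' (OCT-3/4 plus the surface markers SSEA3, SSEA4, TRA-1-60, SSEA1), used to
#' parameterize the simulated four-line study. The 201B7 profile follows the
#' reported quasi-undifferentiated composition (85.2% OCT-3/4, 94.0% SSEA3,
#' 95.0% SSEA4, 87.0% TRA-1-60, 30.2% SSEA1); the other three lines are
#' plausible fixed profiles of the same kind. SSEA1 marks early
#' differentiation and so associates negatively with OCT-3/4; the other
#' surface markers associate positively.
#'
#' @return Tibble with columns `line`, `marker`, `oct4_frac`, `marker_frac`,
#'   `association`.
#' @export
line_marker_profiles <- function() {
  surface <- c("SSEA3", "SSEA4", "TRA-1-60", "SSEA1")
  prof <- list(
    `201B7` = list(oct4 = 0.852, y = c(0.940, 0.950, 0.870, 0.302)),
    `253G1` = list(oct4 = 0.900, y = c(0.920, 0.960, 0.890, 0.180)),
    Tic     = list(oct4 = 0.780, y = c(0.860, 0.900, 0.820, 0.420)),
    H9      = list(oct4 = 0.950, y = c(0.965, 0.975, 0.940, 0.100)))
  purrr::map_dfr(names(prof), function(ln) {
    tibble(line = ln, marker = surface,
           oct4_frac = prof[[ln]]$oct4,
           marker_frac = prof[[ln]]$y,
           association = ifelse(surface == "SSEA1", "negative", "positive"))
  })
}
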