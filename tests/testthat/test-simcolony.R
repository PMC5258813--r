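test_that("identical configuration reproduces bit-identical fields and truth", {
  cfg <- tiny_config(seed = 11)
  a <- generate_colony_field(cfg)
  b <- generate_colony_field(cfg)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
})

test_that("empty field configurations give background-only images", {
  cfg <- sim_config(field_shape = c(64L, 64L), n_colonies = 0L,
                    n_delaminated = 0L, seed = 3)
  out <- generate_colony_field(cfg)
  expect_equal(nrow(out$truth), 0)
  nuc <- out$field$channels$nuclear
  expect_true(abs(mean(nuc) - cfg$background_level) < 3)
  expect_lt(sd(as.numeric(nuc)), 2 * cfg$background_noise_sd)
})

test_that("camera contract holds: integer counts clipped at 2^bits - 1", {
  cfg <- tiny_config(seed = 5, nuclear_amplitude = 1e6)  # force saturation
  out <- generate_colony_field(cfg)
  for (ch in out$field$channels) {
    expect_true(is.integer(ch))
    expect_gte(min(ch), 0)
    expect_lte(max(ch), 2^cfg$camera_bit_depth - 1)
  }
  expect_equal(2^cfg$camera_bit_depth, 4096)  # 12-bit default: 4096 levels
  expect_equal(max(out$field$channels$nuclear), 4095)
})

test_that("ground truth respects ids, packing and footprint invariants", {
  cfg <- tiny_config(seed = 21)
  tr <- generate_colony_field(cfg)$truth
  expect_identical(tr$cell_id, seq_len(nrow(tr)))
  spacing <- cfg$packing_min_spacing * 2 * cfg$nucleus_radius_mean
  d <- as.matrix(dist(cbind(tr$row, tr$col)))
  diag(d) <- Inf
  expect_gte(min(d), spacing - 1e-9)
  incol <- tr[tr$colony_id > 0, ]
  expect_true(all(incol$edge_dist_norm >= 0 & incol$edge_dist_norm <= 1))
  expect_true(all(is.na(tr$edge_dist_norm[tr$colony_id == 0])))
})

test_that("phenotype marginals converge to the configured mixture", {
  f <- quadrant_fractions(0.852, 0.302, "negative")
  expect_equal(sum(f), 1, tolerance = 1e-12)
  phen <- character(0)
  for (s in 1:7) {
    cfg <- sim_config(seed = 100 + s,
                      phenotype_fractions = f)
    phen <- c(phen, generate_colony_field(cfg, render = FALSE)$truth$phenotype)
  }
  expect_gte(length(phen), 2000)
  for (k in names(f)) {
    p_hat <- mean(phen == k)
    ci <- 3 * sqrt(f[[k]] * (1 - f[[k]]) / length(phen))
    expect_lt(abs(p_hat - f[[k]]), ci + 0.01)
  }
})

test_that("differentiated cells concentrate at colony boundaries when biased", {
  tr <- NULL
  for (s in 1:2) {
    cfg <- sim_config(seed = 300 + s, edge_bias = 2)
    tr <- rbind(tr, generate_colony_field(cfg, render = FALSE)$truth)
  }
  incol <- tr[tr$colony_id > 0, ]
  expect_gte(nrow(incol), 500)
  diff_cls <- c("y_single_pos", "double_neg")
  d_diff <- mean(incol$edge_dist_norm[incol$phenotype %in% diff_cls])
  d_und <- mean(incol$edge_dist_norm[!incol$phenotype %in% diff_cls])
  expect_lt(d_diff, d_und)
})

test_that("infeasible packing and invalid configurations raise clear errors", {
  expect_error(generate_colony_field(tiny_config(nucleus_density = 0.05)),
               "packing")
  expect_error(sim_config(field_shape = c(0L, 10L)), "zero-area")
  expect_error(sim_config(phenotype_fractions = c(double_pos = 0.5,
                                                  x_single_pos = 0.5,
                                                  y_single_pos = 0.2,
                                                  double_neg = -0.2)),
               "sum to 1|>= 0")
})

test_that("noise-free flow readings reproduce true expression and fractions", {
  cfg <- tiny_config(seed = 9, flow_cv = 0)
  sim <- generate_colony_field(cfg, render = FALSE)
  fl <- simulate_flow_readings(sim$truth, cfg)
  expect_false(identical(fl$cell_id, sim$truth$cell_id))  # shuffled
  j <- match(fl$cell_id, sim$truth$cell_id)
  expect_equal(fl$x, sim$truth$expr_x[j])
  expect_equal(fl$y, sim$truth$expr_y[j])
  thr <- 150
  expect_equal(mean(fl$y > thr), mean(sim$truth$expr_y > thr))
})

test_that("flow readings clip at the 4-decade ceiling of 10,000", {
  cfg <- tiny_config(seed = 9)
  sim <- generate_colony_field(cfg, render = FALSE)
  tr <- sim$truth
  ## far enough above the ceiling that multiplicative noise cannot dip below
  tr$expr_x <- tr$expr_x + 100 * 10^cfg$flow_decades
  fl <- simulate_flow_readings(tr, cfg)
  expect_true(all(fl$x == 10000))
  expect_true(all(fl$y >= 0 & fl$y <= 10000))
  tr$expr_y[1] <- -1
  expect_error(simulate_flow_readings(tr, cfg), "negative")
})

test_that("flow positive fraction matches the quadrature oracle", {
  ## mixture: fraction f positive lognormal(mu1, s1), rest lognormal(mu0, s0),
  ## times mean-one multiplicative lognormal noise at the configured CV
  cfg <- tiny_config(seed = 13, nucleus_density = 0.0045)
  f <- 0.3; mu1 <- log(600); s1 <- 0.4; mu0 <- log(30); s0 <- 0.5
  cv <- cfg$flow_cv
  sn <- sqrt(log(1 + cv^2))
  t0 <- 150
  ## product of lognormals is lognormal; integrate the mixture tail
  tail_ln <- function(mu, s) {
    1 - stats::integrate(function(u)
      stats::dlnorm(u, meanlog = mu - sn^2 / 2, sdlog = sqrt(s^2 + sn^2)),
      0, t0)$value
  }
  expected <- f * tail_ln(mu1, s1) + (1 - f) * tail_ln(mu0, s0)
  ## Monte-Carlo through the simulator at n ~ 10,000
  fracs <- quadrant_fractions(0.852, f, "positive")
  hits <- 0; n <- 0
  for (s in 1:8) {
    cc <- sim_config(seed = 400 + s, phenotype_fractions = fracs)
    sim <- generate_colony_field(cc, render = FALSE)
    fl <- simulate_flow_readings(sim$truth, cc)
    hits <- hits + sum(fl$y > t0); n <- n + nrow(fl)
  }
  expect_gte(n, 2000)
  mc_err <- 4 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(hits / n - expected), mc_err + 0.01)
})

test_that("quadrant_fractions reproduces requested marginals", {
  for (assoc in c("positive", "negative", "independent")) {
    f <- quadrant_fractions(0.7, 0.4, assoc)
    expect_equal(unname(f["double_pos"] + f["x_single_pos"]), 0.7)
    expect_equal(unname(f["double_pos"] + f["y_single_pos"]), 0.4)
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1)
  }
})
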