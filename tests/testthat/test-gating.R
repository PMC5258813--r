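make_cells <- function(x, y = NULL) {
  out <- tibble::tibble(cell_id = seq_along(x), mean_x = x)
  if (!is.null(y)) out$mean_y <- y
  out
}

test_that("control-quantile thresholds match the sort-and-interpolate oracle", {
  expect_equal(fit_threshold(make_cells(rep(0, 50)), "x")$threshold, 0)
  expect_equal(fit_threshold(make_cells(rep(7, 50)), "x", q = 0.2)$threshold, 7)
  expect_equal(fit_threshold(make_cells(rep(7, 50)), "x", q = 1)$threshold, 7)
  set.seed(4)
  v <- rlnorm(1000, log(30), 0.5)
  g <- fit_threshold(make_cells(v), "x", q = 0.995)
  expect_identical(g$threshold, sort_interpolate_quantile(v, 0.995))
  expect_equal(g$control_n, 1000L)
  expect_error(fit_threshold(make_cells(numeric(0)), "x"), "empty")
  expect_error(fit_threshold(make_cells(v), "x", q = 0), "q must")
  expect_error(fit_threshold(make_cells(v), "x", q = 1.2), "q must")
  expect_error(fit_threshold(make_cells(v), "z"), "channel")
})

test_that("quadrant classification partitions cells exactly", {
  cells <- make_cells(c(0, 10, 0, 10), c(0, 0, 10, 10))
  gx <- structure(list(channel = "x", threshold = 5), class = "gate_spec")
  gy <- structure(list(channel = "y", threshold = 5), class = "gate_spec")
  qr <- classify_quadrants(cells, gx, gy)
  expect_equal(unname(qr$percentages), rep(25, 4))
  expect_equal(sum(qr$counts), 4)
  expect_equal(qr$cells$quadrant,
               c("double_neg", "x_single_pos", "y_single_pos", "double_pos"))
  ## thresholds above every value -> all double negative
  hi <- structure(list(channel = "x", threshold = 99), class = "gate_spec")
  hiy <- structure(list(channel = "y", threshold = 99), class = "gate_spec")
  expect_equal(unname(classify_quadrants(cells, hi, hiy)$percentages["double_neg"]),
               100)
  expect_error(classify_quadrants(make_cells(1:3), gx, gy), "channel")
})

test_that("percentages always sum to 100 and marginals match percent_positive", {
  set.seed(9)
  for (rep in 1:5) {
    cells <- make_cells(rlnorm(200, 4, 1), rlnorm(200, 4, 1))
    gx <- fit_threshold(cells, "x", q = runif(1, 0.3, 0.9))
    gy <- fit_threshold(cells, "y", q = runif(1, 0.3, 0.9))
    qr <- classify_quadrants(cells, gx, gy)
    expect_equal(sum(qr$percentages), 100, tolerance = 1e-9)
    expect_equal(unname(qr$percentages["double_pos"] +
                          qr$percentages["x_single_pos"]),
                 percent_positive(cells, gx))
    expect_equal(unname(qr$percentages["double_pos"] +
                          qr$percentages["y_single_pos"]),
                 percent_positive(cells, gy))
  }
})

test_that("percent_positive uses strict inequality and decreases in the threshold", {
  cells <- make_cells(c(rep(10, 3), rep(1, 7)))
  g <- function(t) structure(list(channel = "x", threshold = t),
                             class = "gate_spec")
  expect_equal(percent_positive(cells, g(5)), 30)
  expect_equal(percent_positive(cells, g(10)), 0)   # ties count negative
  expect_equal(percent_positive(cells, g(0.5)), 100)
  set.seed(2)
  v <- make_cells(rlnorm(300, 3, 1))
  prev <- 100
  for (t in sort(rlnorm(20, 3, 1))) {
    p <- percent_positive(v, g(t))
    expect_lte(p, prev + 1e-12)
    prev <- p
  }
  expect_error(percent_positive(make_cells(numeric(0)), g(1)), "empty")
})

test_that("log-binned histograms conserve counts and match hand binning", {
  g <- structure(list(channel = "x", threshold = 50), class = "gate_spec")
  cells <- make_cells(rep(100, 12))
  h <- expression_histogram(cells, "x", g, n_bins = 16)
  expect_equal(sum(h$count), 12)
  expect_equal(sum(h$count > 0), 1)
  ## toy 6 values, 3 bins over [1, 1000]
  vals <- c(2, 5, 30, 80, 400, 900)
  h3 <- expression_histogram(make_cells(vals), "x", g, n_bins = 3,
                             ceiling_val = 1000)
  edges <- exp(seq(log(1), log(1000), length.out = 4))
  hand <- sapply(1:3, function(b)
    sum(vals >= edges[b] & (vals < edges[b + 1] | (b == 3 & vals <= 1000))))
  expect_equal(h3$count, hand)
  expect_equal(h3$count_positive + h3$count_negative, h3$count)
  expect_equal(sum(h3$count_positive), sum(vals > 50))
  expect_error(expression_histogram(make_cells(vals), "x", g, n_bins = 0),
               "n_bins")
})

test_that("tidy and glance summarize quadrant results", {
  cells <- make_cells(c(1, 10, 10), c(1, 1, 10))
  gx <- structure(list(channel = "x", threshold = 5), class = "gate_spec")
  gy <- structure(list(channel = "y", threshold = 5), class = "gate_spec")
  qr <- classify_quadrants(cells, gx, gy)
  td <- tidy(qr)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$percent), 100)
  gl <- glance(qr)
  expect_equal(gl$total_n, 3)
  expect_equal(gl$pct_x_positive, 100 * 2 / 3, tolerance = 1e-9)
})
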