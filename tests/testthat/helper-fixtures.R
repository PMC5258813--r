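# Fixtures and independent oracles shared across tests. Everything here is
# deliberately naive (loops, flood fill, hand formulas) so it stays
# independent of the package's implementation paths.

# Paint a radially symmetric Gaussian spot into a matrix (independent of the
# package's renderer; used to construct known nuclei).
paint_spot <- function(img, r0, c0, radius, peak, sigma_frac = 0.45) {
  sig <- sigma_frac * radius
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    d2 <- (r - 1 - r0)^2 + (c - 1 - c0)^2
    if (d2 <= (2 * radius)^2)
      img[r, c] <- img[r, c] + peak * exp(-d2 / (2 * sig^2))
  }
  img
}

# Brute-force 4-connected flood fill labeling of a logical mask.
flood_fill_labels <- function(mask) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  lab <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] && out[r, c] == 0L) {
      lab <- lab + 1L
      queue <- list(c(r, c))
      out[r, c] <- lab
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && out[q[1], q[2]] == 0L) {
            out[q[1], q[2]] <- lab
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  out
}

# Brute-force union-find single-linkage components over pairwise distances.
union_find_components <- function(pts, linkage) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= linkage) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Hand implementation of the type-7 (linear interpolation) quantile.
sort_interpolate_quantile <- function(v, q) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Closed-form Pearson r from explicit sums.
hand_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Small default-like config scaled for fast unit tests.
tiny_config <- function(seed = 1L, ...) {
  sim_config(field_shape = c(256L, 256L), n_colonies = 1L,
             colony_radius_range = c(55, 70), n_delaminated = 4L,
             seed = seed, ...)
}
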