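# Independent oracles used across the suite.

# Brute-force monotone least squares: enumerate all partitions of 1..n into
# consecutive blocks, fit each block by its mean, keep partitions whose block
# means are non-decreasing, and take the minimum SSE. Exponential, so n <= 8.
brute_monotone_ls <- function(y) {
  n <- length(y)
  if (n == 1L) return(y)
  stopifnot(n <= 8L)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
    bounds <- c(0L, cuts, n)
    fit <- numeric(n); prev <- -Inf; ok <- TRUE
    for (b in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[b] + 1L):bounds[b + 1L]
      m <- mean(y[idx])
      if (m < prev - 1e-12) { ok <- FALSE; break }
      fit[idx] <- m; prev <- m
    }
    if (!ok) next
    sse <- sum((fit - y)^2)
    if (sse < best_sse - 1e-15) { best_sse <- sse; best <- fit }
  }
  best
}

# Independent trigonometric oracle for the hypsometer formulas, written from
# the geometry (horizontal distance x tangent sums) rather than the formulas
# under test.
oracle_height_base_bar <- function(A, C, WO, WU, K) {
  horiz <- A * C * cos(WU * pi / 180)^2
  rise_top <- horiz * sin(WO * pi / 180) / cos(WO * pi / 180)
  rise_mark <- horiz * sin(WU * pi / 180) / cos(WU * pi / 180)
  rise_top + rise_mark + K
}
oracle_height_slope <- function(D, WO, WU, K) {
  horiz <- D * cos(WU * pi / 180)
  horiz * sin(WO * pi / 180) / cos(WO * pi / 180) +
    horiz * sin(WU * pi / 180) / cos(WU * pi / 180) + K
}

# regular grid positions with optional noise, for raster-fit tests
grid_positions <- function(nx, ny, sx, sy, noise = 0, origin = c(0, 0),
                           theta = 0) {
  g <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  xy <- cbind(g$i * sx, g$j * sy) %*% t(R)
  data.frame(x = origin[1] + xy[, 1] + rnorm(nrow(g), 0, noise),
             y = origin[2] + xy[, 2] + rnorm(nrow(g), 0, noise))
}

# tiny disc-growth fixture: one breast-height disc with the given per-year
# ring widths (mm), equal in all four directions
make_disc_growth <- function(years, ring_mm, h = 1.3) {
  ir <- data.frame(plot = 1L, tree = 1L, disc = 1L,
                   dir = rep(c("N", "E", "S", "W"), each = length(years)),
                   year = rep(years, 4L), ir = rep(ring_mm * 100, 4L))
  dg <- data.frame(plot = 1L, tree = 1L, disc = 1L, h = h)
  disc_growth(ir, dg)
}
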