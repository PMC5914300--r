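test_that("an exact grid is recovered with zero residual", {
  pos <- grid_positions(10, 10, 1.5, 1.5)
  fit <- fit_raster(pos, spacing = c(1.4, 1.6))
  expect_equal(fit$spacing_x, 1.5, tolerance = 1e-9)
  expect_equal(fit$spacing_y, 1.5, tolerance = 1e-9)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-9)
})

test_that("spacing recovery converges as mapping noise shrinks", {
  for (sigma in c(0.1, 0.05, 0.01, 0)) {
    set.seed(101)
    pos <- grid_positions(10, 10, 1.5, 1.5, noise = sigma)
    fit <- fit_raster(pos, spacing = c(1.5, 1.5))
    expect_lt(abs(fit$spacing_x - 1.5), max(4 * sigma / sqrt(100), 1e-9))
    expect_lt(abs(fit$spacing_y - 1.5), max(4 * sigma / sqrt(100), 1e-9))
  }
})

test_that("the fit is invariant to translation and recovers small rotations", {
  set.seed(102)
  pos <- grid_positions(8, 12, 1.0, 2.0, noise = 0.03)
  f1 <- fit_raster(pos, spacing = c(1, 2))
  pos2 <- pos
  pos2$x <- pos$x + 137.2; pos2$y <- pos$y - 59.1
  f2 <- fit_raster(pos2, spacing = c(1, 2))
  expect_equal(f1$spacing_x, f2$spacing_x, tolerance = 1e-9)
  expect_equal(f1$spacing_y, f2$spacing_y, tolerance = 1e-9)

  set.seed(103)
  theta <- 2 * pi / 180
  pos3 <- grid_positions(10, 10, 1.5, 1.5, noise = 0.02, theta = theta)
  f3 <- fit_raster(pos3, spacing = c(1.5, 1.5))
  expect_lt(abs(f3$orientation - theta), 0.005)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_raster(data.frame(x = 1:3, y = 1:3), c(1, 1)), "at least 4")
  expect_error(fit_raster(data.frame(x = 1:10, y = 2 * (1:10)), c(1, 1)),
               "collinear")
})

test_that("serpentine numbering places a skipped number at its node", {
  # 4x3 grid, trees numbered boustrophedon; tree 7 missing
  nc <- 4L; nr <- 3L
  nodes <- serpentine_node(1:12, n_cols = nc)
  pos <- data.frame(x = nodes[, "i"] * 1.5, y = nodes[, "j"] * 1.5)
  present <- setdiff(1:12, 7L)
  fit <- fit_raster(pos[present, ], spacing = c(1.5, 1.5))
  est <- estimate_removed_positions(7L, fit, extent = c(nc, nr),
                                    occupied = fit$nodes,
                                    numbering = list(n_cols = nc), seed = 1)
  expect_true(est$matched)
  expect_equal(c(est$i, est$j), unname(nodes[7, ]))
  expect_equal(c(est$x, est$y), unname(unlist(pos[7, ])), tolerance = 1e-6)
})

test_that("placement fails when no vacant node remains", {
  nodes <- serpentine_node(1:12, n_cols = 4L)
  pos <- data.frame(x = nodes[, "i"], y = nodes[, "j"] * 2)
  fit <- fit_raster(pos, spacing = c(1, 2))
  expect_error(
    estimate_removed_positions(13L, fit, extent = c(4L, 3L),
                               occupied = fit$nodes,
                               numbering = list(n_cols = 4L)),
    "vacant")
})

test_that("random placement is reproducible under a fixed seed", {
  nodes <- serpentine_node(1:20, n_cols = 5L)
  present <- setdiff(1:20, c(3L, 11L, 17L))
  pos <- data.frame(x = nodes[present, "i"], y = nodes[present, "j"])
  fit <- fit_raster(pos, spacing = c(1, 1))
  # out-of-pattern numbers force random placement
  a <- estimate_removed_positions(c(101L, 102L, 103L), fit, c(5L, 4L),
                                  fit$nodes, list(n_cols = 5L), seed = 9)
  b <- estimate_removed_positions(c(101L, 102L, 103L), fit, c(5L, 4L),
                                  fit$nodes, list(n_cols = 5L), seed = 9)
  expect_identical(a, b)
  expect_false(any(a$matched))
  expect_equal(anyDuplicated(paste(a$i, a$j)), 0L)
})

test_that("serpentine recovery places most removed trees at their true node", {
  set.seed(104)
  hits <- 0L; total <- 0L
  for (rep in 1:10) {
    nc <- 10L; nr <- 10L
    nodes <- serpentine_node(1:100, n_cols = nc)
    removed <- sort(sample(1:100, 20L))
    present <- setdiff(1:100, removed)
    pos <- data.frame(x = nodes[present, "i"] * 1.5 + rnorm(80, 0, 0.05),
                      y = nodes[present, "j"] * 1.5 + rnorm(80, 0, 0.05))
    fit <- fit_raster(pos, spacing = c(1.5, 1.5))
    est <- estimate_removed_positions(removed, fit, c(nc, nr), fit$nodes,
                                      list(n_cols = nc), seed = rep)
    hits <- hits + sum(est$i == nodes[removed, "i"] &
                       est$j == nodes[removed, "j"])
    total <- total + 20L
  }
  expect_gte(hits / total, 0.95)
})

test_that("corners snap to mid-row lines and areas follow the shoelace rule", {
  pos <- grid_positions(10, 10, 1.0, 1.0)
  fit <- fit_raster(pos, spacing = c(1, 1))
  good <- data.frame(x = c(-0.5, 9.5, 9.5, -0.5),
                     y = c(-0.5, -0.5, 9.5, 9.5))
  cc <- correct_corners(good, fit)
  expect_false(any(cc$corners$cor))
  expect_equal(cc$area, 100)
  # corner displaced 0.2 m off the mid-row line snaps back
  off <- good
  off$x[1] <- -0.3
  cc2 <- correct_corners(off, fit)
  expect_true(cc2$corners$cor[1])
  expect_equal(cc2$corners$x[1], -0.5, tolerance = 1e-9)
  expect_equal(cc2$area, 100)
  # unit square has unit area
  sq <- data.frame(x = c(-0.5, 0.5, 0.5, -0.5), y = c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(correct_corners(sq, fit)$area, 1)
})
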