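test_that("height decreases are kept only when a crown break explains them", {
  t <- c(1950, 1955, 1960)
  # 12 dm drop with a recorded break: retained
  fl <- filter_height_outliers(t, c(200, 188, 195),
                               broken = c(FALSE, TRUE, FALSE))
  expect_false(any(fl$removed))
  # same drop without a break: later point removed
  fl2 <- filter_height_outliers(t, c(200, 188, 195))
  expect_true(fl2$removed[2])
  expect_false(fl2$removed[3])
  # 9 dm rise over one year is under the rate threshold
  fl3 <- filter_height_outliers(c(1950, 1951), c(200, 209))
  expect_false(any(fl3$removed))
  # 11 dm/yr rise is removed even with a break recorded
  fl4 <- filter_height_outliers(c(1950, 1951), c(200, 211),
                                broken = c(FALSE, TRUE))
  expect_true(fl4$removed[2])
})

test_that("disc height-age splines interpolate between discs", {
  ir <- rbind(
    data.frame(plot = 1L, tree = 1L, disc = 1L, dir = "N",
               year = 1899:1997, ir = 200),
    data.frame(plot = 1L, tree = 1L, disc = 2L, dir = "N",
               year = 1909:1997, ir = 150))
  dg <- disc_growth(ir, data.frame(plot = 1L, tree = 1L, disc = 1:2,
                                   h = c(0.5, 1.5)))
  sp <- disc_height_age(dg, germination_year = 1888)
  # knots: ages 10.5 and 20.5, heights 5 and 15 dm
  expect_equal(sp$age, c(10.5, 20.5))
  expect_equal(sp$h, c(5, 15))
  expect_equal(predict(sp, 10.5), 5)
  mid <- predict(sp, 15.5)
  expect_gt(mid, 5); expect_lt(mid, 15)
  grid_h <- predict(sp, seq(10.5, 20.5, length.out = 200))
  expect_true(all(diff(grid_h) >= -1e-10))
})

test_that("degenerate disc sets are rejected", {
  g1 <- make_disc_growth(1950:1960, ring_mm = rep(2, 11))
  expect_error(disc_height_age(g1, 1888), "two discs")
  # higher disc with an earlier first ring is inconsistent
  ir <- rbind(
    data.frame(plot = 1L, tree = 1L, disc = 1L, dir = "N",
               year = 1920:1997, ir = 100),
    data.frame(plot = 1L, tree = 1L, disc = 2L, dir = "N",
               year = 1910:1997, ir = 100))
  dg <- disc_growth(ir, data.frame(plot = 1L, tree = 1L, disc = 1:2,
                                   h = c(0.5, 5)))
  expect_error(disc_height_age(dg, 1888), "inconsistent")
})

test_that("height levelling recovers a uniform campaign bias", {
  set.seed(51)
  h_ref <- runif(9, 100, 300)
  meas <- data.frame(plot = 1L, tree = 1:9, year = 1970L, h = h_ref * 0.95)
  refs <- data.frame(plot = 1L, tree = 1:9, year = 1970L, h_ref = h_ref)
  lev <- level_height_bias(meas, refs)
  expect_equal(attr(lev, "factors")$factor, 1 / 0.95, tolerance = 1e-12)
  expect_equal(lev$h_lev, h_ref, tolerance = 1e-9)
  # group without references: factor 1, flagged
  meas2 <- rbind(meas, data.frame(plot = 1L, tree = 1L, year = 1980L, h = 250))
  lev2 <- level_height_bias(meas2, refs)
  expect_equal(lev2$h_lev[10], 250)
  expect_true(lev2$lev_flag[10])
})

test_that("campaign-level height bias is recovered within one percent", {
  set.seed(52)
  err <- replicate(100, {
    n <- 40L
    h_ref <- runif(n, 150, 320)
    bias <- runif(1, 0.92, 1.08)
    meas <- data.frame(plot = 1L, tree = seq_len(n), year = 1960L,
                       h = h_ref * bias * rlnorm(n, 0, 0.02))
    refs <- data.frame(plot = 1L, tree = seq_len(n), year = 1960L,
                       h_ref = h_ref)
    attr(level_height_bias(meas, refs), "factors")$factor * bias - 1
  })
  expect_lt(quantile(abs(err), 0.95), 0.01)
})

test_that("the height-age curve refits its own noiseless data", {
  true_par <- c(c0 = 100.58, c1 = 1.1, c2 = -6.578, c3 = 2.0)
  age <- seq(5, 115, by = 5)
  h <- height_age_curve(true_par, age)
  m <- fit_height_age(age, h)
  expect_equal(unname(predict(m, c(35, 70, 100, 109))),
               height_age_curve(true_par, c(35, 70, 100, 109)),
               tolerance = 1e-6)
  expect_lt(m$rss, 1e-8)
})

test_that("the height-age fit rejects degenerate data", {
  expect_error(fit_height_age(c(10, 10, 10, 20), c(5, 5, 5, 5)), "distinct")
})

test_that("ratio smoothing is the identity when heights follow the curve", {
  par <- c(c0 = 100.58, c1 = 1.1, c2 = -6.578, c3 = 2.0)
  model <- structure(list(par = par), class = "height_age_model")
  set.seed(53)
  obs <- expand.grid(tree = paste0("t", 1:12), age = seq(35, 105, by = 10))
  obs$species <- "PCAB"
  obs$d <- 0.3 * height_age_curve(par, obs$age)^1.2
  obs$hMon <- height_age_curve(par, obs$age)
  got <- smooth_height(obs, obs, model, use_xy = FALSE)
  expect_equal(got, obs$hMon, tolerance = 1e-4)
})

test_that("a uniformly taller tree gets its offset back", {
  par <- c(c0 = 100.58, c1 = 1.1, c2 = -6.578, c3 = 2.0)
  model <- structure(list(par = par), class = "height_age_model")
  set.seed(54)
  obs <- expand.grid(tree = paste0("t", 1:15), age = seq(35, 105, by = 10))
  obs$species <- "PCAB"
  obs$d <- 0.3 * height_age_curve(par, obs$age)^1.2
  mult <- ifelse(obs$tree == "t1", 1.10, 1.0)
  obs$hMon <- mult * height_age_curve(par, obs$age) *
    rlnorm(nrow(obs), 0, 0.005)
  got <- smooth_height(obs, obs, model, use_xy = FALSE)
  ratio_t1 <- mean(got[obs$tree == "t1"] /
                     height_age_curve(par, obs$age[obs$tree == "t1"]))
  expect_equal(ratio_t1, 1.10, tolerance = 0.02)
  # never a negative increment within a tree after projection
  for (tr in unique(obs$tree)) {
    idx <- which(obs$tree == tr)
    idx <- idx[order(obs$age[idx])]
    expect_true(all(diff(got[idx]) >= -1e-9))
  }
})

test_that("anchoring reproduces the anchors and interpolates the multiplier", {
  t <- seq(1950, 1990, by = 5)
  smooth <- seq(100, 300, length.out = length(t))
  # identity when anchors sit on the smooth
  expect_equal(anchor_to_observations(t, smooth, t[c(2, 5)], smooth[c(2, 5)]),
               smooth)
  # single anchor: constant multiplier
  got <- anchor_to_observations(t, smooth, t[3], smooth[3] * 1.2)
  expect_equal(got, smooth * 1.2)
  # two anchors 0.95 / 1.05: midpoint multiplier is 1.00
  got2 <- anchor_to_observations(c(0, 1, 2), c(100, 100, 100),
                                 c(0, 2), c(95, 105))
  expect_equal(got2[2], 100)
  expect_equal(got2[c(1, 3)], c(95, 105))
  expect_error(anchor_to_observations(t, smooth * 0, t[1], 100),
               "strictly positive")
})

test_that("final heights are monotone within crown-break segments", {
  t <- seq(1950, 1990, by = 5)
  h <- c(100, 120, 118, 140, 150, 130, 145, 160, 170)
  out <- finalize_heights(t, h, break_times = 1974)
  seg1 <- out[t < 1974]; seg2 <- out[t >= 1974]
  expect_true(all(diff(seg1) >= -1e-9))
  expect_true(all(diff(seg2) >= -1e-9))
  # the decrease across the recorded break is preserved
  expect_lt(seg2[1], seg1[length(seg1)])
  # flat triple resolves through the mean-date knot
  t2 <- c(0, 1, 2, 3, 4)
  h2 <- c(9, 10, 10, 10, 11)
  out2 <- finalize_heights(t2, h2)
  expect_equal(out2, approx(c(0, 2, 4), c(9, 10, 11), xout = t2)$y)
  # strictly increasing input is untouched
  expect_equal(finalize_heights(t, sort(h)), sort(h))
})
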