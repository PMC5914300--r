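test_that("cross measurements average, single readings stand", {
  expect_equal(observed_diameter(100, 110), 105)
  expect_equal(observed_diameter(100, NA), 100)
  expect_equal(observed_diameter(c(100, 80), c(110, NA)), c(105, 80))
  expect_error(observed_diameter(NA, 110), "dbh2 present without dbh")
})

test_that("disc equivalent diameter averages in basal-area space", {
  expect_equal(as.numeric(disc_equivalent_diameter(rep(7, 4))), 14)
  expect_equal(as.numeric(disc_equivalent_diameter(c(10, 10, 20, 20))),
               2 * sqrt(250))
  r <- 12
  expect_equal(as.numeric(disc_equivalent_diameter(c(0, r, r, r))), r * sqrt(3))
  expect_equal(attr(disc_equivalent_diameter(c(5, 5, 5)), "n_radii"), 3L)
})

test_that("ring accrual is linear within the vegetation season", {
  g <- make_disc_growth(1950:1952, ring_mm = c(5, 3, 2))
  # after the season: full rings, times bark factor
  expect_equal(disc_diameter_at_date(g, as.Date("1951-12-31")),
               2 * 8 * 1.070)
  # season start: none of the current ring
  expect_equal(disc_diameter_at_date(g, as.Date("1951-05-01")),
               2 * 5 * 1.070)
  # July 1 is 61 of 123 season days
  expect_equal(disc_diameter_at_date(g, as.Date("1951-07-01")),
               2 * (5 + 3 * 61 / 123) * 1.070)
  expect_error(disc_diameter_at_date(g, as.Date("1949-06-01")), "first ring")
  # bark factor configurable
  expect_equal(disc_diameter_at_date(g, as.Date("1952-12-31"),
                                     bark_factor = 1),
               2 * 10)
})

test_that("median basal-area levelling removes a uniform inflation exactly", {
  set.seed(41)
  d_ref <- runif(12, 80, 300)
  meas <- data.frame(plot = 1L, tree = 1:12, year = 1950L,
                     d = d_ref * sqrt(1.10))   # +10% in basal area
  refs <- data.frame(plot = 1L, tree = 1:12, year = 1950L, d_ref = d_ref)
  lev <- level_systematic_bias(meas, refs)
  expect_equal(lev$d_lev, d_ref, tolerance = 1e-9)
  fac <- attr(lev, "factors")
  expect_equal(fac$median_rel_ba_diff, 0.10, tolerance = 1e-9)
  expect_false(any(lev$lev_flag))
})

test_that("post-levelling group median relative BA difference is exactly zero", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:15, 1L)
    d_ref <- runif(n, 50, 400)
    noise <- rlnorm(n, 0, 0.03)
    meas <- data.frame(plot = 1L, tree = seq_len(n), year = 1960L,
                       d = d_ref * 1.07 * noise)
    refs <- data.frame(plot = 1L, tree = seq_len(n), year = 1960L,
                       d_ref = d_ref)
    lev <- level_systematic_bias(meas, refs)
    ba <- function(d) pi * (d / 2)^2
    rel <- (ba(lev$d_lev) - ba(d_ref)) / ba(d_ref)
    expect_equal(median(rel), 0, tolerance = 1e-12)
  }
})

test_that("groups without references keep factor one and are flagged", {
  meas <- data.frame(plot = c(1L, 1L), tree = 1:2, year = c(1950L, 1955L),
                     d = c(100, 120))
  refs <- data.frame(plot = 1L, tree = 1L, year = 1950L, d_ref = 100)
  lev <- level_systematic_bias(meas, refs)
  expect_equal(lev$d_lev[2], 120)
  expect_true(lev$lev_flag[2])
  expect_false(lev$lev_flag[1])
})

test_that("increment outlier rules fire at the published thresholds", {
  # all increments in range: nothing removed
  t <- seq(1950, 1990, by = 5)
  d <- cumsum(c(100, rep(8 * 5, 8) / 5))
  fl <- filter_diameter_outliers(t, d)
  expect_false(any(fl$removed))
  # one -12 mm drop in a 10-point series is removed
  d2 <- seq(100, 190, by = 10)
  d2[5] <- d2[4] - 12
  fl2 <- filter_diameter_outliers(seq(1950, 1995, by = 5), d2)
  expect_identical(which(fl2$removed), 5L)
  # a 2-point violating series is flagged but retained
  fl3 <- filter_diameter_outliers(c(1950, 1951), c(100, 130))
  expect_true(any(fl3$outlier))
  expect_false(any(fl3$removed))
  # rate rule: -6 mm over one year removed, -6 mm over five years kept
  fl4 <- filter_diameter_outliers(c(1950, 1951, 1952, 1953), c(100, 94, 101, 104))
  expect_true(fl4$removed[2])
  fl5 <- filter_diameter_outliers(c(1950, 1955, 1960, 1965), c(100, 94, 101, 104))
  expect_false(any(fl5$removed))
})

test_that("gap filling is exact at knots and monotone between them", {
  set.seed(43)
  for (rep in 1:25) {
    n <- sample(4:9, 1L)
    t <- sort(sample(seq(1923, 1997, by = 2), n))
    d <- cumsum(runif(n, 0, 20)) + 50
    calendar <- seq(1923, 1997, by = 2) + 0.75
    out <- fill_gaps(t, d, calendar)
    expect_equal(out$d[match(t, out$time)], d, tolerance = 1e-9)
    expect_true(all(diff(out$d) >= -1e-9))
    expect_true(all(out$time >= min(t) & out$time <= max(t)))
  }
  # a gap midway between equal values stays at that value
  out2 <- fill_gaps(c(1950, 1960), c(100, 100), 1955)
  expect_equal(out2$d, rep(100, 3))
})

test_that("monotonization matches the PAVA oracle and linearizes flats", {
  t <- 1:4
  d <- c(10, 12, 11, 13)
  pava <- brute_monotone_ls(d)
  expect_equal(isotone_fit(t, d), pava)
  out <- enforce_monotone(t, d)
  # the flat PAVA pair (11.5, 11.5) is linearized between 10 and 13
  expect_equal(out, approx(c(1, 4), c(10, 13), xout = t)$y)
  # strictly increasing input is untouched
  expect_equal(enforce_monotone(t, c(1, 2, 3, 4)), c(1, 2, 3, 4))
  # constant input is untouched
  expect_equal(enforce_monotone(t, rep(5, 4)), rep(5, 4))
})

test_that("per-tree completion covers every interior campaign monotonically", {
  set.seed(44)
  calendar <- decimal_year(as.Date(sprintf("%d-10-01",
                                           seq(1923, 1997, by = 4))))
  for (rep in 1:10) {
    keep <- sort(sample(seq_along(calendar), 8L))
    t <- calendar[keep]
    d <- cumsum(runif(8, 0, 25)) + 60 + rnorm(8, 0, 3)
    out <- complete_diameter_series(t, d, calendar)
    inner <- calendar[calendar >= min(t) & calendar <= max(t)]
    expect_true(all(inner %in% out$time))
    expect_true(all(diff(out$d) >= -1e-9))
  }
})
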