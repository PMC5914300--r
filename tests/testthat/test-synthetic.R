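test_that("the generator is reproducible and passes its own validation", {
  cfg <- sim_config(n_plots = 2L, n_rows = 5L, n_cols = 5L)
  a <- simulate_stand(cfg, seed = 17)
  b <- simulate_stand(cfg, seed = 17)
  expect_identical(a, b)
  c <- simulate_stand(cfg, seed = 18)
  expect_false(identical(a$tables$dbhObs$dbh, c$tables$dbhObs$dbh))
  expect_equal(nrow(validate_dataset(a$tables)), 0L)
})

test_that("with no noise, bias or missingness the tables equal the truth", {
  cfg <- sim_config(n_plots = 1L, n_rows = 5L, n_cols = 5L,
                    sd_era_d = 0, sd_era_h = 0, tape_offset = 0,
                    cv_d = 0, cv_h = 0, round_d = 0, round_h = 0,
                    heaping = 0, miss_d = 0, p_height = 1, p_crown = 1,
                    sd_pos = 0)
  sim <- simulate_stand(cfg, seed = 4)
  m <- merge(sim$tables$dbhObs, sim$truth$curves,
             by = c("plot", "tree", "year", "obs"))
  expect_gt(nrow(m), 100)
  expect_equal(m$dbh, m$d_true, tolerance = 1e-9)
  # the second (orthogonal) reading exists only in the calliper era
  calliper <- m$year < 1978
  expect_equal(m$dbh2[calliper], m$d_true[calliper], tolerance = 1e-9)
  expect_true(all(is.na(m$dbh2[!calliper])))
  expect_equal(m$ho, m$h_true, tolerance = 1e-9)
  # positions sit exactly on the raster nodes
  expect_equal(sim$tables$pos$x,
               sim$truth$trees$node_x, tolerance = 1e-12)
})

test_that("ring sums reproduce the inside-bark radius year by year", {
  cfg <- sim_config(n_plots = 1L, n_rows = 5L, n_cols = 5L, round_d = 0)
  sim <- simulate_stand(cfg, seed = 8)
  ids <- unique(sim$tables$saDisc[c("plot", "tree")])
  for (r in seq_len(nrow(ids))) {
    p <- ids$plot[r]; tr <- ids$tree[r]
    g <- disc_growth(
      sim$tables$saIr[sim$tables$saIr$plot == p & sim$tables$saIr$tree == tr, ],
      sim$tables$saDisc[sim$tables$saDisc$plot == p &
                          sim$tables$saDisc$tree == tr, ])
    bh <- g$discs[[which.min(vapply(g$discs, `[[`, numeric(1), "h"))]]
    tree_truth <- sim$truth$trees[sim$truth$trees$plot == p &
                                    sim$truth$trees$tree == tr, ]
    # reconstructed outside-bark diameter at season end vs the truth curve
    for (y in range(bh$years)) {
      d_rec <- disc_diameter_at_date(g, as.Date(sprintf("%d-12-31", y)))
      d_true <- sim$config$allom_a * tree_truth$mult_d *
        (tree_truth$mult_h *
           height_age_curve(sim$config$height_par,
                            y - tree_truth$germinationYear))^sim$config$allom_b
      expect_equal(d_rec, d_true, tolerance = 0.02)
    }
  }
})

test_that("calliper-era diameters exceed the inside-bark disc truth by the bark factor", {
  cfg <- sim_config(n_plots = 4L, n_rows = 8L, n_cols = 8L,
                    sd_era_d = 0, heaping = 0, round_d = 0)
  sim <- simulate_stand(cfg, seed = 9)
  m <- merge(sim$tables$dbhObs, sim$truth$curves,
             by = c("plot", "tree", "year", "obs"))
  m <- m[!is.na(m$dbh), ]
  d_ib <- m$d_true / sim$config$bark_factor
  tt <- t.test(m$dbh / d_ib, mu = 1, alternative = "greater")
  expect_lt(tt$p.value, 1e-10)
  expect_equal(mean(m$dbh / d_ib), sim$config$bark_factor, tolerance = 0.01)
})

test_that("recovery scoring reports zero error for the truth itself", {
  sim <- simulate_stand(sim_config(n_plots = 1L, n_rows = 5L, n_cols = 5L),
                        seed = 12)
  truth_out <- data.frame(plot = sim$truth$curves$plot,
                          tree = sim$truth$curves$tree,
                          year = sim$truth$curves$year,
                          obs = sim$truth$curves$obs,
                          d = sim$truth$curves$d_true,
                          h = sim$truth$curves$h_true,
                          hCr = sim$truth$curves$hCr_true)
  sc <- score_recovery(sim$truth, truth_out)
  expect_equal(sc$metrics["d", "rmse"], 0, tolerance = 1e-12)
  expect_equal(sum(sc$violations), 0)
  # constant offset shows up as bias and rmse of the same size
  shifted <- truth_out
  shifted$d <- shifted$d + 1
  sc2 <- score_recovery(sim$truth, shifted)
  expect_equal(sc2$metrics["d", "bias"], 1, tolerance = 1e-12)
  expect_equal(sc2$metrics["d", "rmse"], 1, tolerance = 1e-12)
  expect_error(score_recovery(sim$truth, transform(truth_out, plot = 99L)),
               "overlap")
})

test_that("truth curves are monotone except across breaks", {
  sim <- simulate_stand(sim_config(n_plots = 2L, n_rows = 6L, n_cols = 6L,
                                   break_p = 0.3), seed = 13)
  cv <- sim$truth$curves
  for (key in unique(paste(cv$plot, cv$tree))) {
    sub <- cv[paste(cv$plot, cv$tree) == key, ]
    expect_true(all(diff(sub$d_true) >= -1e-9))
    expect_true(all(diff(sub$h_nb_true) >= -1e-9))
    expect_true(all(diff(sub$hCr_true) >= -1e-9))
    expect_true(all(sub$hCr_true <= sub$h_true + 1e-9))
  }
})
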