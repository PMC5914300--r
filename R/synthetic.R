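## Ground-truthed synthetic spacing trial. The generator lays trees on exact
## planting rasters (the four historical spacings), grows each from a
## four-parameter height-age curve with a lognormal tree effect, derives
## diameter by allometry, and observes the truth through era-specific
## instruments: calliper (crosswise, two readings) until 1973, tape from
## 1978, with per-campaign bias, multiplicative noise, rounding and digit
## heaping. Thinning, crown breaks and stem discs are simulated so that every
## published input table can be emitted and every pipeline stage scored by
## recovery against the stored truth.

#' Default simulation configuration
#'
#' The defaults mirror the structure of a century-long spruce spacing trial:
#' four plots at 1x1, 1.5x1.5, 1x2 and 2x2 m spacing, campaigns from 1923 to
#' 1997 at 1-6 year intervals, calliper then tape diameter eras, and stem
#' discs cut from a few felled trees per plot. Extents are kept small
#' (`n_rows` x `n_cols` trees per plot) so that full-pipeline runs stay
#' cheap; all rates and magnitudes are overridable.
#'
#' @param n_plots number of plots (1-4, taking the first spacings).
#' @param n_rows,n_cols raster extent per plot (trees).
#' @param campaign_years campaign calendar years.
#' @param height_par true height-age parameters (c0, c1, c2, c3), dm scale.
#' @param allom_a,allom_b diameter allometry `d_mm = a * h_dm^b`.
#' @param bark_factor outside-bark unshrunk / inside-bark shrunk diameter.
#' @param sd_tree_h,sd_tree_d lognormal sd of per-tree height/diameter
#'   multipliers.
#' @param sd_era_d,sd_era_h sd of the per-campaign relative instrument bias.
#' @param tape_offset extra relative bias of tape vs calliper diameters.
#' @param cv_d,cv_h per-measurement relative noise.
#' @param round_d,round_h rounding unit (1 = published unit, 0 = none).
#' @param heaping probability that a diameter reading is rounded to the
#'   nearest 5 mm instead of 1 mm (0.286 makes terminal digits 0 and 5 about
#'   three times as frequent as the rest).
#' @param miss_d probability a standing tree misses a diameter campaign.
#' @param p_height probability a measured tree also gets a height.
#' @param p_crown probability a height-measured tree gets a crown base.
#' @param thin_rate per-campaign removal probability (from the 2nd campaign).
#' @param break_p probability a tree suffers one crown break.
#' @param break_drop relative height loss at a crown break.
#' @param n_disc_trees stem-analysis trees per plot.
#' @param sd_pos mapping noise of measured stem positions, m.
#' @param fixed_bias_d optional fixed relative diameter bias applied to every
#'   campaign instead of the random era draws (the tape offset still adds).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_plots = 4L, n_rows = 8L, n_cols = 8L,
                       campaign_years = c(1923, 1925, 1927, 1929, 1933, 1936,
                                          1940, 1944, 1947, 1952, 1960, 1965,
                                          1970, 1973, 1978, 1983, 1989, 1993,
                                          1997),
                       height_par = c(c0 = 100.58, c1 = 1.1,
                                      c2 = -6.578, c3 = 2.0),
                       allom_a = 0.32, allom_b = 1.2, bark_factor = 1.070,
                       sd_tree_h = 0.06, sd_tree_d = 0.08,
                       sd_era_d = 0.02, sd_era_h = 0.03, tape_offset = 0.012,
                       cv_d = 0.015, cv_h = 0.03,
                       round_d = 1, round_h = 1, heaping = 0.286,
                       miss_d = 0.05, p_height = 0.5, p_crown = 0.8,
                       thin_rate = 0.10, break_p = 0.08, break_drop = 0.15,
                       n_disc_trees = 2L, sd_pos = 0.05,
                       fixed_bias_d = NULL) {
  spacings <- list(c(1, 1), c(1.5, 1.5), c(1, 2), c(2, 2))
  stopifnot(n_plots >= 1L, n_plots <= 4L,
            all(c(miss_d, p_height, p_crown, thin_rate, break_p, heaping) >= 0),
            all(c(miss_d, p_height, p_crown, thin_rate, break_p, heaping) <= 1),
            all(c(sd_tree_h, sd_tree_d, sd_era_d, sd_era_h, cv_d, cv_h,
                  sd_pos) >= 0))
  structure(list(
    plots = lapply(seq_len(n_plots), function(p)
      list(plot = p, spacing = spacings[[p]], n_rows = n_rows,
           n_cols = n_cols, offset = c((p - 1) * 200, 0))),
    campaign_years = campaign_years,
    germination_year = c(PCAB = 1888, other = 1892),
    height_par = height_par, allom_a = allom_a, allom_b = allom_b,
    bark_factor = bark_factor,
    sd_tree_h = sd_tree_h, sd_tree_d = sd_tree_d,
    sd_era_d = sd_era_d, sd_era_h = sd_era_h, tape_offset = tape_offset,
    cv_d = cv_d, cv_h = cv_h,
    round_d = round_d, round_h = round_h, heaping = heaping,
    miss_d = miss_d, p_height = p_height, p_crown = p_crown,
    thin_rate = thin_rate, break_p = break_p, break_drop = break_drop,
    n_disc_trees = n_disc_trees, sd_pos = sd_pos,
    fixed_bias_d = fixed_bias_d,
    tape_from = 1978), class = "sim_config")
}

season_fraction_decimal <- function(t) {
  doy <- (t - floor(t)) * 365.25
  pmin(pmax((doy - 121) / 123, 0), 1)
}

# annual envelope interpolated through the vegetation season: value at t is
# E(floor(t)-1) + season_fraction * ring of year floor(t)
seasonal_value <- function(t, envelope_fun) {
  y <- floor(t)
  e_prev <- envelope_fun(y - 1)
  e_cur <- envelope_fun(y)
  e_prev + season_fraction_decimal(t) * (e_cur - e_prev)
}

round_heap <- function(x, unit, heaping) {
  if (unit <= 0) return(x)
  to5 <- stats::runif(length(x)) < heaping
  ifelse(to5, round(x / (5 * unit)) * 5 * unit, round(x / unit) * unit)
}

campaign_dates <- function(years) {
  # mostly autumn surveys, every fourth campaign mid-season
  mid <- seq_along(years) %% 4L == 0L
  as.Date(sprintf("%d-%s", years, ifelse(mid, "07-01", "10-01")))
}

tree_truth_funs <- function(cfg, mult_h, mult_d, germ, break_time = NA,
                            break_drop = 0.15) {
  curve_end <- function(y) {
    age <- pmax(y - germ, 0)
    ifelse(age <= 0, 0, mult_h * height_age_curve(cfg$height_par, pmax(age, 1e-9)))
  }
  h_nb <- function(t) seasonal_value(t, curve_end)
  d_env <- function(y) mult_d * cfg$allom_a * curve_end(y)^cfg$allom_b
  list(
    h_nb = h_nb,
    h = function(t) {
      base <- h_nb(t)
      if (!is.na(break_time)) {
        f <- ifelse(t >= break_time,
                    1 - break_drop * exp(-(t - break_time) / 20), 1)
        base <- base * f
      }
      base
    },
    d = function(t) seasonal_value(t, d_env),
    hCr = function(t) {
      age <- pmax(t - germ, 0)
      ratio <- pmax(0.7 - 0.5 * exp(-age / 50), 0)
      ratio * h_nb(t)
    })
}

fixed_lonlat <- function(x, y) {
  # fixed-affine projection stub (degrees per metre at the trial latitude)
  list(lon = 16.1353 + (x - 0) * 1.345e-5, lat = 48.2254 + (y - 0) * 8.99e-6)
}

#' Simulate a ground-truthed spacing-trial dataset
#'
#' Generates the published input tables (`corner`, `area`, `pos`, `date`,
#' `dbhObs`, `crown`, `secDiam`, `saTree`, `saIr`, `saDisc`) plus a
#' `dhcComplSmooth` table holding the truth sampled at the campaign dates,
#' together with the ground truth needed to score pipeline recovery. The
#' same seed reproduces the dataset exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `tables` (named list of data.frames in the published
#'   schemas), `truth` (per-tree attributes, truth curves at campaign dates,
#'   era bias table, true parameters) and `config`.
#' @export
simulate_stand <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  years <- cfg$campaign_years
  dates <- campaign_dates(years)
  tdec <- decimal_year(dates)
  n_camp <- length(years)
  calliper <- years < cfg$tape_from

  era <- data.frame(
    year = years, obs = 1L, date = dates, time = tdec,
    instrument = ifelse(calliper, "calliper", "tape"),
    bias_d = (if (is.null(cfg$fixed_bias_d))
                stats::rnorm(n_camp, 0, cfg$sd_era_d)
              else rep(cfg$fixed_bias_d, n_camp)) +
             ifelse(calliper, 0, cfg$tape_offset),
    bias_h = stats::rnorm(n_camp, 0, cfg$sd_era_h))

  pos_rows <- list(); corner_rows <- list(); area_rows <- list()
  date_rows <- list(); dbh_rows <- list(); crown_rows <- list()
  sa_tree <- list(); sa_ir <- list(); sa_disc <- list(); sec_rows <- list()
  truth_trees <- list(); truth_curves <- list(); dhc_truth <- list()

  species_pool <- c("PCAB", "LADC", "PNSY", "FASY", "QCPE", "BTPE")

  for (pl in cfg$plots) {
    p <- pl$plot; sx <- pl$spacing[1]; sy <- pl$spacing[2]
    nr <- pl$n_rows; nc <- pl$n_cols
    n_tree <- nr * nc
    node <- serpentine_node(seq_len(n_tree), n_cols = nc)
    x0 <- pl$offset[1]; y0 <- pl$offset[2]
    node_x <- x0 + node[, "i"] * sx
    node_y <- y0 + node[, "j"] * sy

    species <- ifelse(stats::runif(n_tree) < 0.95, "PCAB",
                      sample(species_pool[-1], n_tree, replace = TRUE))
    germ <- ifelse(species == "PCAB", cfg$germination_year["PCAB"],
                   cfg$germination_year["other"])
    mult_h <- stats::rlnorm(n_tree, 0, cfg$sd_tree_h)
    mult_d <- stats::rlnorm(n_tree, 0, cfg$sd_tree_d)

    # thinning: removal campaign per tree (NA = survives)
    remove_camp <- rep(NA_integer_, n_tree)
    standing <- rep(TRUE, n_tree)
    for (k in 2:(n_camp - 1L)) {
      out <- standing & stats::runif(n_tree) < cfg$thin_rate
      remove_camp[out] <- k
      standing[out] <- FALSE
    }
    removeal <- ifelse(is.na(remove_camp), NA_integer_,
                       sample(c(1L, 2L, 9L), n_tree, replace = TRUE,
                              prob = c(0.7, 0.1, 0.2)))
    # crown breaks: at most one, uniform within the tree's standing period
    has_break <- stats::runif(n_tree) < cfg$break_p
    last_camp <- ifelse(is.na(remove_camp), n_camp, remove_camp)
    break_time <- rep(NA_real_, n_tree)
    for (i in which(has_break & last_camp > 3L)) {
      bk <- sample(3:last_camp[i], 1L)
      break_time[i] <- tdec[bk] - stats::runif(1, 0.2, 1.5)
    }

    funs <- lapply(seq_len(n_tree), function(i)
      tree_truth_funs(cfg, mult_h[i], mult_d[i], germ[i], break_time[i],
                      cfg$break_drop))

    pos_noise_x <- stats::rnorm(n_tree, 0, cfg$sd_pos)
    pos_noise_y <- stats::rnorm(n_tree, 0, cfg$sd_pos)
    pos_obs <- is.na(remove_camp)  # mapped late in the trial
    px <- node_x + ifelse(pos_obs, pos_noise_x, 0)
    py <- node_y + ifelse(pos_obs, pos_noise_y, 0)
    ll <- fixed_lonlat(px, py)
    pos_rows[[p]] <- data.frame(
      plot = p, tree = seq_len(n_tree), x = px, y = py,
      z = 320 + 0.02 * (px - x0) + 0.01 * (py - y0),
      species = species, posObs = pos_obs,
      germinationYear = as.integer(germ), core = TRUE,
      removeDate = as.Date(ifelse(is.na(remove_camp), NA,
                                  dates[remove_camp]), origin = "1970-01-01"),
      removeal = removeal, lon = ll$lon, lat = ll$lat)

    w <- (nc - 1) * sx; hgt <- (nr - 1) * sy
    cx <- x0 + c(-sx / 2, w + sx / 2, w + sx / 2, -sx / 2)
    cy <- y0 + c(-sy / 2, -sy / 2, hgt + sy / 2, hgt + sy / 2)
    cll <- fixed_lonlat(cx, cy)
    corner_rows[[p]] <- data.frame(plot = p, corner = 1:4, cor = FALSE,
                                   x = cx, y = cy, lon = cll$lon, lat = cll$lat)
    area_rows[[p]] <- data.frame(plot = p, area = (w + sx) * (hgt + sy))
    date_rows[[p]] <- data.frame(plot = p, year = years, obs = 1L, date = dates)

    # observations
    for (k in seq_len(n_camp)) {
      alive <- which(is.na(remove_camp) | remove_camp >= k)
      if (!length(alive)) next
      seen <- alive[stats::runif(length(alive)) >= cfg$miss_d]
      if (!length(seen)) next
      t0 <- tdec[k]
      d_true <- vapply(seen, function(i) funs[[i]]$d(t0), numeric(1))
      h_true <- vapply(seen, function(i) funs[[i]]$h(t0), numeric(1))
      c_true <- vapply(seen, function(i) funs[[i]]$hCr(t0), numeric(1))
      bias_d <- era$bias_d[k]; bias_h <- era$bias_h[k]
      if (calliper[k]) {
        dbh1 <- round_heap(d_true * (1 + bias_d) *
                             (1 + stats::rnorm(length(seen), 0, cfg$cv_d)),
                           cfg$round_d, cfg$heaping)
        dbh2 <- round_heap(d_true * (1 + bias_d) *
                             (1 + stats::rnorm(length(seen), 0, cfg$cv_d)),
                           cfg$round_d, cfg$heaping)
      } else {
        dbh1 <- round_heap(d_true * (1 + bias_d) *
                             (1 + stats::rnorm(length(seen), 0, cfg$cv_d)),
                           cfg$round_d, cfg$heaping)
        dbh2 <- rep(NA_real_, length(seen))
      }
      hm <- stats::runif(length(seen)) < cfg$p_height
      ho <- rep(NA_real_, length(seen))
      ho[hm] <- h_true[hm] * (1 + bias_h) *
        (1 + stats::rnorm(sum(hm), 0, cfg$cv_h))
      if (cfg$round_h > 0) ho[hm] <- round(ho[hm] / cfg$round_h) * cfg$round_h
      cm <- hm & stats::runif(length(seen)) < cfg$p_crown
      ka <- rep(NA_real_, length(seen))
      ka[cm] <- pmin(c_true[cm] * (1 + stats::rnorm(sum(cm), 0, cfg$cv_h)),
                     ho[cm])
      if (cfg$round_h > 0) ka[cm] <- round(ka[cm] / cfg$round_h) * cfg$round_h
      crown_code <- rep(0L, length(seen))
      for (ii in seq_along(seen)) {
        bt <- break_time[seen[ii]]
        if (!is.na(bt) && t0 >= bt &&
            (k == 1L || tdec[k - 1L] < bt))
          crown_code[ii] <- 1L
      }
      dbh_rows[[length(dbh_rows) + 1L]] <- data.frame(
        plot = p, tree = seen, year = years[k], obs = 1L,
        dbh = dbh1, dbh2 = dbh2,
        hmk = ifelse(hm, 1L, NA_integer_), kh = ifelse(hm, 0L, NA_integer_),
        ho = ho, ka = ka, kb = NA_real_, wka = NA_real_,
        kraft = sample(1:5, length(seen), replace = TRUE,
                       prob = c(0.1, 0.3, 0.3, 0.2, 0.1)),
        crown = crown_code, stem = 0L, defoliation = NA_integer_)
      # crown radii in the mapping campaign
      if (years[k] == 1989 || (max(years) < 1989 && k == n_camp)) {
        rad <- matrix(stats::rlnorm(length(seen) * 8, log(pmax(h_true, 10) * 0.012),
                                    0.2), ncol = 8)
        crown_rows[[length(crown_rows) + 1L]] <- data.frame(
          plot = p, tree = seen, year = years[k], obs = 1L,
          d17 = rad[, 1], d62 = rad[, 2], d107 = rad[, 3], d152 = rad[, 4],
          d197 = rad[, 5], d242 = rad[, 6], d287 = rad[, 7], d332 = rad[, 8])
      }
    }

    # truth curves at campaign dates (between first campaign and removal)
    for (i in seq_len(n_tree)) {
      kk <- seq_len(if (is.na(remove_camp[i])) n_camp else remove_camp[i])
      truth_curves[[length(truth_curves) + 1L]] <- data.frame(
        plot = p, tree = i, year = years[kk], obs = 1L, time = tdec[kk],
        d_true = vapply(tdec[kk], funs[[i]]$d, numeric(1)),
        h_true = vapply(tdec[kk], funs[[i]]$h, numeric(1)),
        h_nb_true = vapply(tdec[kk], funs[[i]]$h_nb, numeric(1)),
        hCr_true = vapply(tdec[kk], funs[[i]]$hCr, numeric(1)))
    }
    truth_trees[[p]] <- data.frame(
      plot = p, tree = seq_len(n_tree), species = species,
      germinationYear = germ, mult_h = mult_h, mult_d = mult_d,
      break_time = break_time,
      remove_time = ifelse(is.na(remove_camp), NA, tdec[remove_camp]),
      node_x = node_x, node_y = node_y)

    # stem-analysis trees: felled late, long ring series
    late_removed <- which(!is.na(remove_camp) & remove_camp >= n_camp - 6L)
    pool <- if (length(late_removed) >= cfg$n_disc_trees) late_removed
            else order(-ifelse(is.na(remove_camp), n_camp, remove_camp))[
              seq_len(min(cfg$n_disc_trees, n_tree))]
    disc_trees <- if (length(pool) > cfg$n_disc_trees)
      sample(pool, cfg$n_disc_trees) else pool
    for (i in disc_trees) {
      fell_k <- if (is.na(remove_camp[i])) n_camp else remove_camp[i]
      fell_year <- years[fell_k]
      f <- funs[[i]]
      # 1.3 m calibration disc: rings from the year the tip passed 13 dm
      yrs_all <- (germ[i] + 1):fell_year
      h_mid <- vapply(yrs_all + 121.5 / 365.25 + 61 / 365.25, f$h_nb, numeric(1))
      reach_13 <- yrs_all[which(h_mid >= 13)[1]]
      ring_years <- reach_13:fell_year
      r_end <- vapply(ring_years, function(y) f$d(y + 0.9) / 2 / cfg$bark_factor,
                      numeric(1))
      ir_mm <- diff(c(0, r_end))
      e <- stats::runif(1, 0, 0.08)
      dir_mult <- c(1 + e, 1 - e, 1 + e, 1 - e) / sqrt(1 + e^2)
      disc_id <- 1L
      sa_disc[[length(sa_disc) + 1L]] <- data.frame(
        plot = p, tree = i, disc = disc_id, h = 1.3)
      for (dd in 1:4) {
        sa_ir[[length(sa_ir) + 1L]] <- data.frame(
          plot = p, tree = i, disc = disc_id, dir = c("N", "E", "S", "W")[dd],
          year = ring_years, ir = round(ir_mm * dir_mult[dd] * 100, 0))
      }
      # higher discs every 50 dm for the height-age spline
      h_fell <- f$h_nb(tdec[fell_k])
      disc_h_dm <- seq(50, max(h_fell - 30, 60), by = 50)
      for (j in seq_along(disc_h_dm)) {
        hd <- disc_h_dm[j]
        hit <- which(h_mid >= hd)
        if (!length(hit)) next
        y1 <- yrs_all[hit[1]]
        if (y1 >= fell_year) next
        disc_id <- disc_id + 1L
        sa_disc[[length(sa_disc) + 1L]] <- data.frame(
          plot = p, tree = i, disc = disc_id, h = hd / 10)
        ry <- y1:fell_year
        r_end_j <- vapply(ry, function(y) 0.8 * f$d(y + 0.9) / 2 / cfg$bark_factor,
                          numeric(1))
        r_end_j <- r_end_j - r_end_j[1] + ir_mm[1]
        sa_ir[[length(sa_ir) + 1L]] <- data.frame(
          plot = p, tree = i, disc = disc_id, dir = "N", year = ry,
          ir = round(diff(c(0, pmax(r_end_j, 0.01))) * 100, 0))
      }
      sa_tree[[length(sa_tree) + 1L]] <- data.frame(
        plot = p, tree = i, species = species[i],
        dbh = round(f$d(tdec[fell_k]) / 10, 1),
        height = round(f$h(tdec[fell_k]) / 10, 1),
        hKrown = round(f$hCr(tdec[fell_k]) / 10, 1))
      len_m <- f$h(tdec[fell_k]) / 10
      taper <- function(hm) ifelse(hm < len_m,
        f$d(tdec[fell_k]) / 10 * ((len_m - hm) / (len_m - 1.3))^0.7, NA_real_)
      mcols <- stats::setNames(as.list(round(taper(1:27), 1)), paste0("m", 1:27))
      sec_rows[[length(sec_rows) + 1L]] <- do.call(data.frame, c(list(
        plot = p, tree = i, year = fell_year, species = species[i],
        length = round(len_m, 1), dbh = round(f$d(tdec[fell_k]) / 10, 1),
        crownLength = round((f$h(tdec[fell_k]) - f$hCr(tdec[fell_k])) / 10, 1),
        crownWidth = round(stats::rlnorm(1, log(3), 0.2), 1)), mcols))
    }
  }

  curves <- do.call(rbind, truth_curves)
  # dhcComplSmooth-schema table carrying the truth at campaign dates
  h_round <- round(curves$h_true, 1)
  dhc <- data.frame(plot = curves$plot, tree = curves$tree,
                    year = curves$year, obs = curves$obs,
                    d = round(curves$d_true, 1),
                    h = h_round,
                    hCr = pmin(round(curves$hCr_true, 1), h_round))

  tables <- list(
    corner = do.call(rbind, corner_rows),
    area = do.call(rbind, area_rows),
    pos = do.call(rbind, pos_rows),
    date = do.call(rbind, date_rows),
    dbhObs = do.call(rbind, dbh_rows),
    crown = if (length(crown_rows)) do.call(rbind, crown_rows) else NULL,
    secDiam = if (length(sec_rows)) do.call(rbind, sec_rows) else NULL,
    saTree = if (length(sa_tree)) do.call(rbind, sa_tree) else NULL,
    saIr = if (length(sa_ir)) do.call(rbind, sa_ir) else NULL,
    saDisc = if (length(sa_disc)) do.call(rbind, sa_disc) else NULL,
    dhcComplSmooth = dhc)
  tables <- Filter(Negate(is.null), tables)
  for (nm in names(tables)) {
    sch <- dc_schemas()[[nm]]
    for (col in setdiff(names(sch$columns), names(tables[[nm]])))
      tables[[nm]][[col]] <- NA
    tables[[nm]] <- tables[[nm]][, names(sch$columns)]
    rownames(tables[[nm]]) <- NULL
  }

  list(tables = tables,
       truth = list(trees = do.call(rbind, truth_trees), curves = curves,
                    era = era,
                    par = list(height = cfg$height_par,
                               allom = c(a = cfg$allom_a, b = cfg$allom_b),
                               bark_factor = cfg$bark_factor)),
       config = cfg)
}

#' Write a simulated dataset as CSV files
#'
#' @param tables the `tables` element of [simulate_stand()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stand <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables))
    write_table(tables[[nm]], nm, file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' Score pipeline output against the generator truth
#'
#' Joins the processed series to the truth curves at the campaign dates and
#' reports per-variable RMSE and bias, the coverage of expected slots, and
#' invariant violations (non-monotone diameter, non-monotone height outside
#' recorded breaks, crown base above height).
#'
#' @param truth the `truth` element of [simulate_stand()].
#' @param output a `dhcComplSmooth`-schema data.frame (e.g. from
#'   [process_stand()]).
#' @return list with `metrics` (data.frame: variable, rmse, bias, n),
#'   `coverage`, and `violations` (named counts).
#' @export
score_recovery <- function(truth, output) {
  m <- merge(truth$curves, output,
             by = c("plot", "tree", "year", "obs"))
  if (!nrow(m)) stop("no overlap between truth and output tree identities")
  metric <- function(est, tru) {
    ok <- !is.na(est) & !is.na(tru)
    c(rmse = sqrt(mean((est[ok] - tru[ok])^2)),
      bias = mean(est[ok] - tru[ok]), n = sum(ok))
  }
  mets <- rbind(d = metric(m$d, m$d_true),
                h = metric(m$h, m$h_true),
                hCr = metric(m$hCr, m$hCr_true))
  viol <- c(d_nonmonotone = 0L, h_nonmonotone = 0L, hCr_nonmonotone = 0L,
            crown_above_height = 0L, missing_in_range = 0L)
  brk <- truth$trees
  for (key in unique(paste(output$plot, output$tree))) {
    sub <- output[paste(output$plot, output$tree) == key, ]
    sub <- sub[order(sub$year, sub$obs), ]
    if (anyNA(sub$d) || anyNA(sub$h) || anyNA(sub$hCr))
      viol["missing_in_range"] <- viol["missing_in_range"] + 1L
    if (any(diff(sub$d) < -1e-6))
      viol["d_nonmonotone"] <- viol["d_nonmonotone"] + 1L
    bt <- brk$break_time[paste(brk$plot, brk$tree) == key]
    tt <- truth$curves$time[match(paste(sub$plot, sub$tree, sub$year),
                                  paste(truth$curves$plot, truth$curves$tree,
                                        truth$curves$year))]
    dec <- which(diff(sub$h) < -1e-6)
    if (length(dec)) {
      # a decrease is legitimate only in the one interval containing the break
      ok_break <- length(bt) == 1L && !is.na(bt) && length(dec) == 1L &&
        !anyNA(tt[c(dec, dec + 1L)]) &&
        bt > tt[dec] - 1e-9 && bt <= tt[dec + 1L] + 1e-9
      if (!ok_break) viol["h_nonmonotone"] <- viol["h_nonmonotone"] + 1L
    }
    if (any(diff(sub$hCr) < -1e-6))
      viol["hCr_nonmonotone"] <- viol["hCr_nonmonotone"] + 1L
    if (any(sub$hCr > sub$h + 1e-6))
      viol["crown_above_height"] <- viol["crown_above_height"] + 1L
  }
  list(metrics = as.data.frame(mets), coverage = nrow(m) / nrow(output),
       violations = viol)
}
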