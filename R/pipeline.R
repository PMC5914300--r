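## End-to-end orchestration: from the raw input tables to the completed,
## bias-corrected, monotone diameter/height/crown-base series in the
## dhcComplSmooth schema. Stage order follows the curation narrative:
## diameters (level -> filter -> isoreg -> gap fill), then heights (filter ->
## disc levelling -> hMon -> height-age curve -> ratio smoothing -> anchor ->
## finalize, with and without crown breaks), then the crown base (monotone
## observations -> dual spline estimate -> average -> anchor -> clip).

tree_key <- function(plot, tree) paste(plot, tree, sep = ":")

#' Disc-derived reference series for calibration
#'
#' For every stem-analysis tree, computes the outside-bark reference
#' diameter (breast-height disc, ring accrual within the season) at each of
#' the tree's measurement dates, and the disc-spline reference height at
#' each campaign age inside the spline's knot range.
#'
#' @param tables named list of input tables (needs `saIr`, `saDisc`, `pos`,
#'   `date`).
#' @param bark_factor inside-bark to outside-bark factor (default 1.070).
#' @return list with `d_ref` (plot, tree, year, d_ref in mm) and `h_ref`
#'   (plot, tree, year, h_ref in dm); zero-row frames when no discs exist.
#' @export
disc_references <- function(tables, bark_factor = 1.070) {
  empty_d <- data.frame(plot = integer(0), tree = integer(0),
                        year = integer(0), d_ref = numeric(0))
  empty_h <- data.frame(plot = integer(0), tree = integer(0),
                        year = integer(0), h_ref = numeric(0))
  if (is.null(tables$saDisc) || !nrow(tables$saDisc))
    return(list(d_ref = empty_d, h_ref = empty_h))
  cal <- tables$date
  cal$time <- decimal_year(cal$date)
  d_rows <- list(); h_rows <- list()
  ids <- unique(tables$saDisc[c("plot", "tree")])
  for (r in seq_len(nrow(ids))) {
    p <- ids$plot[r]; tr <- ids$tree[r]
    g <- disc_growth(
      tables$saIr[tables$saIr$plot == p & tables$saIr$tree == tr, ],
      tables$saDisc[tables$saDisc$plot == p & tables$saDisc$tree == tr, ])
    camp <- cal[cal$plot == p, ]
    # breast-height disc reference diameters
    bh <- g$discs[[which.min(vapply(g$discs, `[[`, numeric(1), "h"))]]
    for (k in seq_len(nrow(camp))) {
      yr <- as.integer(format(camp$date[k], "%Y"))
      if (yr < bh$years[1] || yr > bh$years[length(bh$years)]) next
      d_rows[[length(d_rows) + 1L]] <- data.frame(
        plot = p, tree = tr, year = camp$year[k],
        d_ref = disc_diameter_at_date(g, camp$date[k],
                                      bark_factor = bark_factor))
    }
    germ <- tables$pos$germinationYear[tables$pos$plot == p &
                                       tables$pos$tree == tr]
    if (length(germ) == 1L && !is.na(germ) && length(g$discs) >= 2L) {
      sp <- tryCatch(disc_height_age(g, germ), error = function(e) NULL)
      if (!is.null(sp)) {
        age <- camp$time - germ
        ok <- age >= min(sp$age) & age <= max(sp$age)
        if (any(ok))
          h_rows[[length(h_rows) + 1L]] <- data.frame(
            plot = p, tree = tr, year = camp$year[ok],
            h_ref = predict(sp, age[ok]))
      }
    }
  }
  list(d_ref = if (length(d_rows)) do.call(rbind, d_rows) else empty_d,
       h_ref = if (length(h_rows)) do.call(rbind, h_rows) else empty_h)
}

extract_heights <- function(dbh, exclude_hmk = 6L) {
  out <- dbh
  out$h_obs <- NA_real_
  out$hCr_obs <- NA_real_
  kh0 <- !is.na(out$kh) & out$kh == 0L
  out$h_obs[kh0] <- out$ho[kh0]
  out$hCr_obs[kh0] <- out$ka[kh0]
  kh1 <- !is.na(out$kh) & out$kh == 1L & !is.na(out$ho) &
         !is.na(out$ka) & !is.na(out$kb)
  if (any(kh1)) {
    out$h_obs[kh1] <- height_slope_distance(D = out$ho[kh1],
                                            WO = out$ka[kh1] / 10,
                                            WU = out$kb[kh1] / 10)
    wk <- kh1 & !is.na(out$wka)
    out$hCr_obs[wk] <- height_slope_distance(D = out$ho[wk],
                                             WO = out$wka[wk] / 10,
                                             WU = out$kb[wk] / 10)
  }
  drop <- !is.na(out$hmk) & out$hmk %in% exclude_hmk
  out$h_obs[drop] <- NA_real_
  out$hCr_obs[drop] <- NA_real_
  out
}

#' Run the full curation pipeline on a loaded dataset
#'
#' Produces the completed, monotone individual-tree series: diameter at
#' every campaign between each tree's first and last observation, height
#' with and without crown-break segmentation, and the crown base bounded by
#' the tree height.
#'
#' @param tables named list of input tables (`pos`, `date`, `dbhObs` and
#'   optionally `saIr`/`saDisc` for disc calibration).
#' @param min_keep minimum surviving diameter observations before outlier
#'   removal, see [filter_diameter_outliers()].
#' @param k basis dimension of the penalized smooths.
#' @param min_obs_re observations below which a tree's intercept offset
#'   falls back to its species.
#' @param break_codes crown-quality codes treated as crown breaks.
#' @param bark_factor disc-to-outside-bark diameter factor.
#' @return list with `result` (a `dhcComplSmooth`-schema data.frame, plus a
#'   `h_nobreak` column), `height_age` (the fitted [fit_height_age()]
#'   model), `level_d`, `level_h` (the per-group calibration factors) and
#'   `series` (the per-tree completed grids with all intermediate columns).
#' @export
process_stand <- function(tables, min_keep = 3L, k = 6, min_obs_re = 3L,
                          break_codes = c(1L, 2L, 6L), bark_factor = 1.070) {
  stopifnot(all(c("pos", "date", "dbhObs") %in% names(tables)))
  cal <- tables$date
  cal$time <- decimal_year(cal$date)
  pos <- tables$pos
  dbh <- merge(tables$dbhObs, cal[c("plot", "year", "obs", "time", "date")],
               by = c("plot", "year", "obs"))
  dbh <- dbh[order(dbh$plot, dbh$tree, dbh$time), ]
  dbh$d_obs <- observed_diameter(dbh$dbh, dbh$dbh2)
  dbh <- extract_heights(dbh)
  dbh$key <- tree_key(dbh$plot, dbh$tree)
  pos$key <- tree_key(pos$plot, pos$tree)
  dbh$germ <- pos$germinationYear[match(dbh$key, pos$key)]
  dbh$species <- pos$species[match(dbh$key, pos$key)]
  dbh$x <- pos$x[match(dbh$key, pos$key)]
  dbh$y <- pos$y[match(dbh$key, pos$key)]
  dbh$age <- dbh$time - dbh$germ
  dbh$broken <- !is.na(dbh$crown) & dbh$crown %in% break_codes

  ## ---- diameters ----
  refs <- disc_references(tables, bark_factor = bark_factor)
  dm <- dbh[!is.na(dbh$d_obs), c("plot", "tree", "year", "obs", "time", "key")]
  dm$d <- dbh$d_obs[!is.na(dbh$d_obs)]
  lev <- level_systematic_bias(dm, refs$d_ref)
  dm$d_lev <- lev$d_lev

  grid <- list()   # completed per-tree series
  for (ky in unique(dm$key)) {
    sub <- dm[dm$key == ky, ]
    sub <- sub[order(sub$time), ]
    calendar <- cal$time[cal$plot == sub$plot[1]]
    comp <- if (nrow(sub) >= 2L)
      complete_diameter_series(sub$time, sub$d_lev, calendar,
                               min_keep = min_keep)
    else data.frame(time = sub$time, d = sub$d_lev, filled = FALSE)
    comp$key <- ky
    comp$plot <- sub$plot[1]; comp$tree <- sub$tree[1]
    grid[[ky]] <- comp
  }
  grid <- do.call(rbind, grid)
  grid$year <- cal$year[match(paste(grid$plot, round(grid$time, 4)),
                              paste(cal$plot, round(cal$time, 4)))]
  grid$obs <- cal$obs[match(paste(grid$plot, round(grid$time, 4)),
                            paste(cal$plot, round(cal$time, 4)))]
  grid$germ <- pos$germinationYear[match(grid$key, pos$key)]
  grid$species <- pos$species[match(grid$key, pos$key)]
  grid$x <- pos$x[match(grid$key, pos$key)]
  grid$y <- pos$y[match(grid$key, pos$key)]
  grid$age <- grid$time - grid$germ

  ## ---- heights ----
  hobs <- dbh[!is.na(dbh$h_obs) & dbh$h_obs > 0, ]
  kept <- list()
  for (ky in unique(hobs$key)) {
    sub <- hobs[hobs$key == ky, ]
    sub <- sub[order(sub$time), ]
    fl <- filter_height_outliers(sub$time, sub$h_obs, sub$broken)
    kept[[ky]] <- sub[!fl$removed, ]
  }
  hobs <- do.call(rbind, kept)
  hm <- hobs[c("plot", "tree", "year", "obs", "time", "key", "age",
               "species", "x", "y", "broken")]
  hm$h <- hobs$h_obs
  levh <- level_height_bias(hm, refs$h_ref)
  hm$h_lev <- levh$h_lev

  # per-tree break times (campaign time at which a break was first coded)
  breaks_by_tree <- lapply(split(dbh[dbh$broken, c("time", "key")],
                                 dbh$key[dbh$broken]),
                           function(s) sort(unique(s$time)))
  hm$hMon <- NA_real_
  for (ky in unique(hm$key)) {
    idx <- which(hm$key == ky)
    idx <- idx[order(hm$time[idx])]
    bt <- breaks_by_tree[[ky]] %||% numeric(0)
    hm$hMon[idx] <- finalize_heights(hm$time[idx], hm$h_lev[idx],
                                     break_times = bt - 1e-9)
  }

  # height-age curve from unbroken trees present at the final campaign
  final_year <- tapply(cal$year, cal$plot, max)
  hm$last_year <- tapply(hm$year, hm$key, max)[hm$key]
  unbroken <- !(hm$key %in% names(breaks_by_tree))
  ha_rows <- unbroken & hm$last_year >= final_year[as.character(hm$plot)]
  if (sum(ha_rows) < 8L) ha_rows <- unbroken
  ha_model <- fit_height_age(hm$age[ha_rows], hm$hMon[ha_rows])

  # ratio smoothing over the completed grid
  hm$d <- grid$d[match(paste(hm$key, round(hm$time, 4)),
                       paste(grid$key, round(grid$time, 4)))]
  obs_fit <- hm[!is.na(hm$d), c("key", "species", "age", "d", "x", "y", "hMon")]
  names(obs_fit)[1] <- "tree"
  nd <- grid[c("key", "species", "age", "d", "x", "y")]
  names(nd)[1] <- "tree"
  grid$hSmooth <- smooth_height(obs_fit, nd, ha_model, k = k,
                                min_obs = min_obs_re)

  grid$h <- NA_real_; grid$h_nobreak <- NA_real_
  for (ky in unique(grid$key)) {
    idx <- which(grid$key == ky)
    idx <- idx[order(grid$time[idx])]
    tt <- grid$time[idx]
    hs <- pmax(grid$hSmooth[idx], 1e-6)
    a <- hm[hm$key == ky, ]
    a <- a[order(a$time), ]
    bt <- breaks_by_tree[[ky]] %||% numeric(0)
    anch_all <- a[a$time >= min(tt) - 1e-9 & a$time <= max(tt) + 1e-9, ]
    h_all <- anchor_to_observations(tt, hs, anch_all$time, anch_all$hMon)
    grid$h[idx] <- finalize_heights(tt, h_all, break_times = bt - 1e-9)
    anch_nb <- if (length(bt)) anch_all[anch_all$time < min(bt), ] else anch_all
    h_nb <- anchor_to_observations(tt, hs, anch_nb$time, anch_nb$hMon)
    grid$h_nobreak[idx] <- finalize_heights(tt, h_nb)
  }

  ## ---- crown base ----
  cobs <- dbh[!is.na(dbh$hCr_obs) & dbh$hCr_obs > 0, ]
  cobs$h_at <- grid$h[match(paste(cobs$key, round(cobs$time, 4)),
                            paste(grid$key, round(grid$time, 4)))]
  cobs <- cobs[!is.na(cobs$h_at), ]
  cm <- list()
  for (ky in unique(cobs$key)) {
    sub <- cobs[cobs$key == ky, ]
    sub <- sub[order(sub$time), ]
    mc <- monotone_crown_base(sub$time, sub$hCr_obs, sub$h_at)
    sub$hCr_mon <- mc$hCr_mon
    cm[[ky]] <- sub
  }
  cobs <- if (length(cm)) do.call(rbind, cm) else cobs
  cobs$d_at <- grid$d[match(paste(cobs$key, round(cobs$time, 4)),
                            paste(grid$key, round(grid$time, 4)))]
  cobs$h_nb_at <- grid$h_nobreak[match(paste(cobs$key, round(cobs$time, 4)),
                                       paste(grid$key, round(grid$time, 4)))]
  cfit <- cobs[!is.na(cobs$d_at) & !is.na(cobs$h_nb_at),
               c("key", "species", "age", "d_at", "h_nb_at", "x", "y",
                 "hCr_mon")]
  names(cfit) <- c("tree", "species", "age", "d", "h_nb", "x", "y", "hCr_mon")
  ndc <- grid[c("key", "species", "age", "d", "h_nobreak", "x", "y")]
  names(ndc) <- c("tree", "species", "age", "d", "h_nb", "x", "y")
  est <- estimate_crown_base(cfit, ndc, k = k, min_obs = min_obs_re)
  grid$hCr <- NA_real_
  for (ky in unique(grid$key)) {
    idx <- which(grid$key == ky)
    idx <- idx[order(grid$time[idx])]
    a <- cobs[cobs$key == ky, ]
    a <- a[a$time >= min(grid$time[idx]) - 1e-9 &
           a$time <= max(grid$time[idx]) + 1e-9, ]
    grid$hCr[idx] <- finalize_crown_base(
      grid$time[idx], est$hCr_direct[idx], est$hCr_ratio[idx],
      a$time, a$hCr_mon, grid$h[idx])
  }

  result <- grid[order(grid$plot, grid$tree, grid$time),
                 c("plot", "tree", "year", "obs", "d", "h", "hCr",
                   "h_nobreak")]
  rownames(result) <- NULL
  list(result = result, height_age = ha_model,
       level_d = attr(lev, "factors"), level_h = attr(levh, "factors"),
       series = grid)
}
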