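## Diameter curation: average crosswise calliper readings, derive reference
## diameters from stem-disc ring series, level era-specific instrument bias
## in basal-area space, drop implausible increments, enforce monotone growth
## with isotonic regression, and fill observation gaps with a monotone cubic
## Hermite spline through basal area over decimal years.

#' Single observed diameter from one or two cross-sectional readings
#'
#' Crosswise calliper campaigns recorded two orthogonal diameters; their
#' arithmetic mean is used. Tape campaigns stored the girth-derived diameter
#' directly, so a single value stands as is.
#'
#' @param dbh first diameter reading, mm.
#' @param dbh2 orthogonal second reading, mm, or `NA`.
#' @return diameter in mm.
#' @export
observed_diameter <- function(dbh, dbh2 = NA_real_) {
  if (any(is.na(dbh) & !is.na(dbh2)))
    stop("dbh2 present without dbh")
  stopifnot(all(dbh > 0, na.rm = TRUE))
  ifelse(is.na(dbh2), dbh, (dbh + dbh2) / 2)
}

#' Equivalent diameter of a stem disc from orthogonal radii
#'
#' The four radii (N, E, S, W) are averaged in basal-area space: the
#' equivalent diameter is that of the circle whose area equals the mean of
#' the four per-radius circle areas, i.e. `2 * sqrt(mean(r^2))`.
#'
#' @param radii numeric vector of radii (any length >= 1; normally 4). Fewer
#'   than four radii are used as available and flagged via the `"n_radii"`
#'   attribute.
#' @return equivalent diameter in the unit of `radii`.
#' @export
disc_equivalent_diameter <- function(radii) {
  radii <- radii[!is.na(radii)]
  stopifnot(length(radii) >= 1L, all(radii >= 0))
  structure(2 * sqrt(mean(radii^2)), n_radii = length(radii))
}

#' Assemble per-disc cumulative growth from ring-width tables
#'
#' @param sa_ir `saIr`-schema data.frame (ring widths in 1/100 mm) for one
#'   tree.
#' @param sa_disc `saDisc`-schema data.frame (disc heights in m) for the same
#'   tree.
#' @return object of class `disc_growth`: per disc, the disc height, ring
#'   years, and the cumulative radius (mm) per measurement direction.
#' @export
disc_growth <- function(sa_ir, sa_disc) {
  stopifnot(nrow(sa_ir) > 0, nrow(sa_disc) > 0)
  discs <- lapply(seq_len(nrow(sa_disc)), function(k) {
    id <- sa_disc$disc[k]
    rows <- sa_ir[sa_ir$disc == id, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    dirs <- split(rows, rows$dir)
    years <- sort(unique(rows$year))
    if (any(diff(years) != 1L))
      stop("ring years not consecutive for disc ", id)
    cum <- sapply(dirs, function(dd) {
      dd <- dd[order(dd$year), ]
      if (!identical(dd$year, years)) stop("direction/year mismatch, disc ", id)
      if (any(dd$ir < 0)) stop("negative ring width, disc ", id)
      cumsum(dd$ir) / 100   # 1/100 mm -> mm radius
    })
    list(disc = id, h = sa_disc$h[k], years = years,
         cum_radius = as.matrix(cum))
  })
  discs <- Filter(Negate(is.null), discs)
  structure(list(discs = discs), class = "disc_growth")
}

season_fraction <- function(date) {
  # ring accrual runs linearly May 1 .. Aug 31 (123 days), flat otherwise
  yr <- as.integer(format(date, "%Y"))
  start <- as.Date(sprintf("%d-05-01", yr))
  pmin(pmax(as.numeric(date - start) / 123, 0), 1)
}

#' Outside-bark diameter of a disc at an arbitrary date
#'
#' Within a calendar year the ring accrues linearly from May 1 to August 31
#' and is constant outside that window. The inside-bark equivalent diameter
#' is scaled by `bark_factor` to represent unshrunk wood outside bark.
#'
#' @param growth a `disc_growth` object.
#' @param date a `Date`.
#' @param disc disc number; default the lowest disc (breast height for the
#'   calibration discs).
#' @param bark_factor multiplier from inside-bark shrunk to outside-bark
#'   unshrunk diameter; default 1.070.
#' @return diameter in mm, outside bark.
#' @export
disc_diameter_at_date <- function(growth, date, disc = NULL, bark_factor = 1.070) {
  stopifnot(inherits(growth, "disc_growth"))
  if (is.character(date)) date <- as.Date(date)
  dd <- if (is.null(disc)) {
    growth$discs[[which.min(vapply(growth$discs, `[[`, numeric(1), "h"))]]
  } else {
    hit <- Filter(function(g) g$disc == disc, growth$discs)
    if (!length(hit)) stop("no such disc: ", disc)
    hit[[1]]
  }
  yr <- as.integer(format(date, "%Y"))
  if (yr < dd$years[1]) stop("date before the disc's first ring")
  frac <- season_fraction(date)
  idx_prev <- match(yr - 1L, dd$years)
  idx_cur <- match(min(yr, dd$years[length(dd$years)]), dd$years)
  r_prev <- if (yr > dd$years[length(dd$years)]) dd$cum_radius[idx_cur, ]
            else if (is.na(idx_prev)) rep(0, ncol(dd$cum_radius))
            else dd$cum_radius[idx_prev, ]
  r_cur <- dd$cum_radius[idx_cur, ]
  r <- if (yr > dd$years[length(dd$years)]) r_cur else r_prev + frac * (r_cur - r_prev)
  as.numeric(disc_equivalent_diameter(r)) * bark_factor
}

#' Level era-specific diameter bias against stem-disc references
#'
#' Instrument and observer changes shift whole campaigns. For each group
#' (campaign year x plot) the relative basal-area difference
#' `(BA_measured - BA_reference) / BA_reference` is computed for every tree
#' with a disc-derived reference diameter, and the group median of those
#' differences is removed from all measurements of the group in basal-area
#' space. Groups without any reference keep their values (factor 1) and are
#' flagged.
#'
#' @param measurements data.frame with `plot`, `tree`, `year`, `d` (mm).
#' @param references data.frame with `plot`, `tree`, `year`, `d_ref` (mm,
#'   outside bark, see [disc_diameter_at_date()]).
#' @return `measurements` with added columns `d_lev` (levelled diameter,
#'   mm) and `lev_flag` (`TRUE` when the group had no reference), plus a
#'   `"factors"` attribute with the per-group median relative BA difference.
#' @export
level_systematic_bias <- function(measurements, references) {
  m <- merge(measurements, references, by = c("plot", "tree", "year"),
             all.x = TRUE)
  grp <- interaction(measurements$plot, measurements$year, drop = TRUE)
  grp_m <- interaction(m$plot, m$year, drop = TRUE)
  med <- tapply(seq_len(nrow(m)), grp_m, function(idx) {
    ok <- idx[!is.na(m$d_ref[idx])]
    if (!length(ok)) return(NA_real_)
    rel <- (ba_from_d(m$d[ok]) - ba_from_d(m$d_ref[ok])) / ba_from_d(m$d_ref[ok])
    stats::median(rel)
  })
  f <- as.vector(med[as.character(grp)])
  flag <- is.na(f)
  f[flag] <- 0
  out <- measurements
  out$d_lev <- d_from_ba(ba_from_d(measurements$d) / (1 + f))
  out$lev_flag <- unname(flag)
  attr(out, "factors") <- data.frame(
    group = names(med), median_rel_ba_diff = as.numeric(med))
  out
}

#' Flag and drop implausible diameter increments
#'
#' An observation is an outlier when the increment from the previous kept
#' observation is below -10 mm in total, below -5.4 mm per year, or above
#' +10 mm per year. Outliers are removed only when at least `min_keep`
#' observations survive; otherwise they are flagged but retained.
#'
#' @param time decimal years, strictly increasing.
#' @param d diameters, mm.
#' @param min_keep minimum surviving observations required before removal
#'   (default 3).
#' @param drop_total total negative increment threshold, mm (default -10).
#' @param drop_rate negative rate threshold, mm/yr (default -5.4).
#' @param rise_rate positive rate threshold, mm/yr (default 10).
#' @return data.frame `time`, `d`, `outlier` (flag), `removed` (flag).
#' @export
filter_diameter_outliers <- function(time, d, min_keep = 3L,
                                     drop_total = -10, drop_rate = -5.4,
                                     rise_rate = 10) {
  n <- length(d)
  stopifnot(length(time) == n, n >= 1L)
  flag <- logical(n)
  if (n >= 2L) {
    last <- 1L
    for (i in 2:n) {
      inc <- d[i] - d[last]
      rate <- inc / (time[i] - time[last])
      if (inc < drop_total || rate < drop_rate || rate > rise_rate) {
        flag[i] <- TRUE
      } else last <- i
    }
  }
  removed <- if (n - sum(flag) >= min_keep) flag else rep(FALSE, n)
  data.frame(time = time, d = d, outlier = flag, removed = removed)
}

#' Monotonize a diameter series
#'
#' Isotonic least-squares regression (pool-adjacent-violators via
#' [stats::isoreg()]) of diameter over time, followed by linear
#' interpolation across interior runs of equal values that have strictly
#' smaller and larger neighbours (zero increment over several campaigns is a
#' measurement artefact, not biology).
#'
#' @param time decimal years, non-decreasing.
#' @param d diameters, mm.
#' @return non-decreasing diameters, mm.
#' @export
enforce_monotone <- function(time, d) {
  interpolate_flat_runs(time, isotone_fit(time, d))
}

#' Fill observation gaps in a diameter series
#'
#' Missing campaigns between a tree's first and last observation are filled
#' by monotone cubic Hermite interpolation of basal area over decimal years;
#' the interpolant passes exactly through the observations.
#'
#' @param time decimal years of the observations, strictly increasing.
#' @param d observed diameters, mm.
#' @param calendar decimal years of all campaigns to cover (only those
#'   within the observation range are filled; others are dropped).
#' @return data.frame `time`, `d`, `filled` over the union of observation
#'   and interior calendar dates.
#' @export
fill_gaps <- function(time, d, calendar) {
  stopifnot(length(time) == length(d), length(time) >= 2L)
  inner <- calendar[calendar >= min(time) & calendar <= max(time)]
  allt <- sort(unique(c(time, inner)))
  ba <- monotone_interp(time, ba_from_d(d), allt)
  data.frame(time = allt, d = d_from_ba(ba),
             filled = !(allt %in% time))
}

#' Complete diameter pipeline for one tree
#'
#' Runs the per-tree stages in order: outlier filtering, isotonic
#' monotonization, gap filling at the campaign calendar, a monotonicity
#' re-check, and flat-run linear interpolation. Input diameters are expected
#' to be levelled already (see [level_systematic_bias()]).
#'
#' @param time decimal years, strictly increasing.
#' @param d levelled diameters, mm.
#' @param calendar decimal years of all campaign dates for the plot.
#' @param min_keep see [filter_diameter_outliers()].
#' @return data.frame `time`, `d`, `filled`; `d` non-decreasing and defined
#'   at every campaign date between first and last observation.
#' @export
complete_diameter_series <- function(time, d, calendar, min_keep = 3L) {
  fl <- filter_diameter_outliers(time, d, min_keep = min_keep)
  keep <- !fl$removed
  t2 <- time[keep]; d2 <- d[keep]
  if (length(t2) < 2L)
    return(data.frame(time = t2, d = d2, filled = FALSE))
  d3 <- enforce_monotone(t2, d2)
  out <- fill_gaps(t2, d3, calendar)
  out$d <- enforce_monotone(out$time, out$d)
  out
}
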