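## Technical-validation statistics: digit-preference (heaping) detection on
## the terminal digit of diameters/heights, and the per-hectare stand
## summaries (stem number, quadratic mean and dominant diameter/height,
## basal-area stock, increment and mean annual increment).

#' Chi-square test for digit preference
#'
#' Observers rounding to the nearest 0 or 5 leave a non-uniform distribution
#' of the remainder of the value divided by 10. The observed remainder
#' counts are compared with the uniform expectation by Pearson's chi-square
#' test (df = divisor - 1).
#'
#' @param values integer measurements in their recording unit (mm for
#'   diameters, dm for heights).
#' @param divisor modulus (default 10).
#' @return list with `statistic`, `df`, `p.value` and the remainder `counts`.
#' @export
digit_preference_test <- function(values, divisor = 10L) {
  if (any(values != round(values)))
    stop("values must be integers in their recording unit")
  n <- length(values)
  if (n < 5L * divisor)
    warning("fewer than ", 5L * divisor,
            " values: expected counts below 5, chi-square approximation weak")
  counts <- tabulate(values %% divisor + 1L, nbins = divisor)
  ct <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / divisor, divisor)))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value), counts = counts)
}

#' Per-hectare stand summary at one campaign date
#'
#' Aggregates the processed individual-tree values of the trees standing
#' inside the corrected plot border at one date. `dg` is the quadratic mean
#' diameter (diameter of the tree of mean basal area), `d50`/`h50` the
#' diameter/height of the 50th strongest/tallest tree per hectare (rank
#' scaled by plot area), `hg` the basal-area-weighted mean height.
#'
#' @param d diameters of the standing trees, mm.
#' @param h heights of the standing trees, dm.
#' @param area plot area, m².
#' @param dominant_rank rank per hectare defining the dominant-tree metrics
#'   (default 50).
#' @return one-row data.frame: `n_per_ha`, `dg_cm`, `d50_cm`, `hg_m`,
#'   `h50_m`, `basal_area_m2_ha`.
#' @export
stand_summary <- function(d, h, area, dominant_rank = 50L) {
  if (area <= 0) stop("plot area must be positive")
  stopifnot(length(d) == length(h))
  n <- length(d)
  ba <- ba_from_d(d) / 1e6                 # mm^2 -> m^2
  scale <- 1e4 / area
  rank_needed <- ceiling(dominant_rank * area / 1e4)
  nth <- function(x, k) if (length(x) >= k && k >= 1L)
    sort(x, decreasing = TRUE)[k] else NA_real_
  data.frame(
    n_per_ha = n * scale,
    dg_cm = if (n) d_from_ba(mean(ba_from_d(d / 10))) else NA_real_,
    d50_cm = nth(d, rank_needed) / 10,
    hg_m = if (n && sum(ba) > 0) sum(ba * h) / sum(ba) / 10 else NA_real_,
    h50_m = nth(h, rank_needed) / 10,
    basal_area_m2_ha = sum(ba) * scale)
}

#' Stand development across all campaign dates of one plot
#'
#' Computes the [stand_summary()] per campaign for the trees standing at
#' that date (restricted to those inside the corner polygon when corners
#' are given), plus cumulative removed basal area, periodic annual
#' basal-area increment of total production (standing + removed), and mean
#' annual increment (total production / stand age).
#'
#' @param records data.frame with `tree`, `time` (decimal year), `d` (mm),
#'   `h` (dm) — the completed series of all trees of one plot.
#' @param removals data.frame `tree`, `time` (decimal year of removal), or
#'   `NULL`; a tree is standing at a date strictly before its removal time.
#' @param area plot area, m².
#' @param planting_year decimal year of stand origin, for stand age.
#' @param positions optional data.frame `tree`, `x`, `y`; with `corners`
#'   (data.frame `x`, `y`) restricts trees to the polygon.
#' @param corners optional corner polygon.
#' @param dominant_rank see [stand_summary()].
#' @return data.frame, one row per campaign date: the summary columns plus
#'   `cum_removed_ba_m2_ha`, `pai_m2_ha_yr`, `mai_m2_ha_yr`.
#' @export
stand_development <- function(records, removals = NULL, area,
                              planting_year, positions = NULL,
                              corners = NULL, dominant_rank = 50L) {
  if (area <= 0) stop("plot area must be positive")
  if (!is.null(positions) && !is.null(corners)) {
    inside <- point_in_polygon(positions$x, positions$y,
                               corners$x, corners$y)
    keep <- positions$tree[inside]
    records <- records[records$tree %in% keep, , drop = FALSE]
    if (!is.null(removals))
      removals <- removals[removals$tree %in% keep, , drop = FALSE]
  }
  dates <- sort(unique(records$time))
  scale <- 1e4 / area
  last_ba <- function(tr) {
    rec <- records[records$tree == tr, ]
    if (!nrow(rec)) return(0)
    ba_from_d(rec$d[which.max(rec$time)]) / 1e6
  }
  rows <- vector("list", length(dates))
  prev_total <- NA_real_; prev_t <- NA_real_
  for (k in seq_along(dates)) {
    t0 <- dates[k]
    removed_now <- if (is.null(removals)) integer(0)
                   else unique(removals$tree[removals$time <= t0])
    standing <- setdiff(unique(records$tree), removed_now)
    rec <- records[records$tree %in% standing & records$time == t0, ]
    sm <- stand_summary(rec$d, rec$h, area, dominant_rank)
    cum_removed <- sum(vapply(removed_now, last_ba, numeric(1))) * scale
    total <- sm$basal_area_m2_ha + cum_removed
    age <- t0 - planting_year
    sm$cum_removed_ba_m2_ha <- cum_removed
    sm$pai_m2_ha_yr <- if (is.na(prev_total)) NA_real_
                       else (total - prev_total) / (t0 - prev_t)
    sm$mai_m2_ha_yr <- if (age > 0) total / age else NA_real_
    sm$time <- t0
    rows[[k]] <- sm
    prev_total <- total; prev_t <- t0
  }
  out <- do.call(rbind, rows)
  out[, c("time", setdiff(names(out), "time"))]
}
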