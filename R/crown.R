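## Crown-base curation. Spruce self-prunes: the live crown base only ever
## moves upward, and it can never sit above the tree top. Observations are
## clipped to the concurrent height, monotonized, modelled twice (directly
## and through the crown ratio), averaged, and anchored back onto the
## monotone observations.

#' Monotone crown-base observations
#'
#' Raw crown-base heights are clipped to the concurrent tree height (flagged
#' where clipping was needed) and projected onto non-decreasing values by
#' isotonic least squares.
#'
#' @param time decimal years, non-decreasing.
#' @param hCr raw crown-base heights, dm.
#' @param h concurrent tree heights, dm (same length), or `NULL` to skip
#'   clipping.
#' @return data.frame `time`, `hCr_mon`, `clipped`.
#' @export
monotone_crown_base <- function(time, hCr, h = NULL) {
  stopifnot(length(time) == length(hCr), length(hCr) >= 1L)
  clipped <- rep(FALSE, length(hCr))
  if (!is.null(h)) {
    stopifnot(length(h) == length(hCr))
    clipped <- hCr > h
    hCr <- pmin(hCr, h)
  }
  data.frame(time = time, hCr_mon = isotone_fit(time, hCr), clipped = clipped)
}

#' Dual spline estimate of the crown base
#'
#' Two additive penalized-spline models with per-tree intercept offsets
#' (per-species fallback below `min_obs` observations), both over age,
#' diameter, break-free height and optionally position: one for the crown
#' base directly, one for the crown ratio (crown base / height). The ratio
#' prediction is clipped to [0, 1] before scaling by the break-free height.
#'
#' @param obs data.frame `tree`, `species`, `age`, `d`, `h_nb` (break-free
#'   height, dm), `hCr_mon` and optionally `x`, `y`.
#' @param newdata data.frame with the same covariates at every date to
#'   predict.
#' @param use_xy include the spatial smooth.
#' @param k basis dimension per smooth.
#' @param min_obs per-species fallback threshold.
#' @return data.frame `hCr_direct`, `hCr_ratio` (both dm) for the rows of
#'   `newdata`.
#' @export
estimate_crown_base <- function(obs, newdata,
                                use_xy = all(c("x", "y") %in% names(obs)),
                                k = 6, min_obs = 3L) {
  need <- c("tree", "species", "age", "d", "h_nb")
  for (col in c(need, if (use_xy) c("x", "y")))
    for (df_n in list(obs, newdata))
      if (!col %in% names(df_n)) stop("missing covariate column: ", col)
  if (anyNA(newdata[c(need, if (use_xy) c("x", "y"))]))
    stop("missing covariate value in newdata")
  dat <- obs
  dat$ratio <- pmin(pmax(obs$hCr_mon / obs$h_nb, 0), 1)
  dat$tree_f <- re_factor(dat$tree, dat$species, min_obs)
  ka <- term_k(dat$age, k); kd <- term_k(dat$d, k); kh <- term_k(dat$h_nb, k)
  kxy <- if (use_xy) max(4L, min(k, nrow(unique(dat[c("x", "y")])) - 1L)) else k
  rhs <- "s(age, k = ka) + s(d, k = kd) + s(h_nb, k = kh) + s(tree_f, bs = 're')"
  if (use_xy) rhs <- paste(rhs, "+ s(x, y, k = kxy)")
  g_dir <- fit_gam_safe(stats::as.formula(paste("hCr_mon ~", rhs)), dat)
  g_rat <- fit_gam_safe(stats::as.formula(paste("ratio ~", rhs)), dat)
  nd <- newdata
  nd$tree_f <- factor(ifelse(as.character(nd$tree) %in% levels(dat$tree_f),
                             as.character(nd$tree),
                             paste0("sp:", nd$species)),
                      levels = levels(dat$tree_f))
  unseen <- is.na(nd$tree_f)
  if (any(unseen)) nd$tree_f[unseen] <- levels(dat$tree_f)[1]
  pred_zero_re <- function(g) {
    trm <- mgcv::predict.gam(g, newdata = nd, type = "terms")
    re_col <- grep("tree_f", colnames(trm))
    if (any(unseen) && length(re_col)) trm[unseen, re_col] <- 0
    as.numeric(attr(trm, "constant") + rowSums(trm))
  }
  direct <- pred_zero_re(g_dir)
  ratio <- pmin(pmax(pred_zero_re(g_rat), 0), 1)
  data.frame(hCr_direct = direct, hCr_ratio = ratio * nd$h_nb)
}

#' Finalize the crown-base series of one tree
#'
#' Averages the direct and ratio-based estimates, projects the average onto
#' non-decreasing values, anchors it multiplicatively onto the monotone
#' observations, re-projects, removes interior flat runs via the mean-date
#' rule, and clips to the final tree height. An anchoring or clipping step
#' that would force the crown base to descend raises an error.
#'
#' @param time decimal years of the full series.
#' @param hCr_direct,hCr_ratio the two estimates at `time`, dm.
#' @param anchor_time,anchor_value monotone crown-base observations, dm.
#' @param h_final final tree height at `time`, dm.
#' @return non-decreasing crown-base series, dm, `<= h_final` everywhere.
#' @export
finalize_crown_base <- function(time, hCr_direct, hCr_ratio,
                                anchor_time, anchor_value, h_final) {
  stopifnot(length(hCr_direct) == length(time),
            length(hCr_ratio) == length(time),
            length(h_final) == length(time))
  avg <- (hCr_direct + hCr_ratio) / 2
  avg <- pmax(isotone_fit(time, avg), 1e-6)
  out <- anchor_to_observations(time, avg, anchor_time, anchor_value)
  out <- isotone_fit(time, out)
  out <- interpolate_flat_runs_meandate(time, out)
  over <- out > h_final
  if (any(over)) {
    out <- pmin(out, h_final)
    if (any(diff(out) < -1e-9))
      stop("crown base cannot be reconciled below tree height at time(s) ",
           paste(utils::head(signif(time[over], 7), 3L), collapse = ", "))
  }
  out
}
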