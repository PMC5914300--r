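## Height curation. Heights were measured with poles, ladders and several
## generations of hypsometers; the pipeline removes implausible increments,
## levels campaigns against stem-analysis heights, fits a height-age curve
## on unbroken final-age trees, smooths the ratio of monotone height to the
## curve with penalized splines plus per-tree intercept offsets, and anchors
## the smooth back onto the measured heights.

#' Drop implausible height increments
#'
#' A height observation is removed when it implies a decrease of more than
#' 10 dm since the previous kept observation without a recorded crown break,
#' or an increase of more than 10 dm per year. A crown break (the loss of the
#' tree top) is the one legitimate cause of a height decrease.
#'
#' @param time decimal years, strictly increasing.
#' @param h heights, dm.
#' @param broken logical; `TRUE` where a crown break/damage was recorded at
#'   that observation.
#' @param drop_total decrease threshold, dm (default -10).
#' @param rise_rate increase threshold, dm/yr (default 10).
#' @return data.frame `time`, `h`, `removed`.
#' @export
filter_height_outliers <- function(time, h, broken = rep(FALSE, length(h)),
                                   drop_total = -10, rise_rate = 10) {
  n <- length(h)
  stopifnot(length(time) == n, length(broken) == n, n >= 1L)
  removed <- logical(n)
  if (n >= 2L) {
    last <- 1L
    for (i in 2:n) {
      inc <- h[i] - h[last]
      rate <- inc / (time[i] - time[last])
      if ((inc < drop_total && !broken[i]) || rate > rise_rate) {
        removed[i] <- TRUE
      } else last <- i
    }
  }
  data.frame(time = time, h = h, removed = removed)
}

#' Height over age from a felled tree's stem discs
#'
#' Each disc pins down the age at which the stem tip passed the disc height:
#' the calendar year of the disc's innermost ring, reduced by half a year
#' because the height was reached mid vegetation period. A monotone cubic
#' Hermite spline through the (age, height) knots gives height at any age in
#' between.
#'
#' @param growth a [disc_growth()] object for one tree.
#' @param germination_year calendar year of germination.
#' @return object of class `height_age_spline` with `age` (yr), `h` (dm)
#'   knots and `predict(object, age)` support.
#' @export
disc_height_age <- function(growth, germination_year) {
  stopifnot(inherits(growth, "disc_growth"))
  discs <- growth$discs
  if (length(discs) < 2L) stop("at least two discs with ring counts required")
  h <- vapply(discs, `[[`, numeric(1), "h") * 10        # m -> dm
  y1 <- vapply(discs, function(d) d$years[1], numeric(1))
  ord <- order(h)
  h <- h[ord]; y1 <- y1[ord]
  if (any(diff(y1) <= 0))
    stop("inconsistent ring counts: a higher disc has an earlier first ring")
  age <- (y1 - germination_year) - 0.5
  structure(list(age = age, h = h), class = "height_age_spline")
}

#' @export
predict.height_age_spline <- function(object, age, ...) {
  monotone_interp(object$age, object$h, age)
}

#' Level height campaigns against stem-analysis heights
#'
#' For each plot x campaign-year group, the factor is the median over
#' reference trees of (stem-analysis height / measured height); all measured
#' heights of the group are multiplied by it. Groups without a reference
#' keep factor 1 and are flagged.
#'
#' @param measurements data.frame `plot`, `tree`, `year`, `h` (dm).
#' @param references data.frame `plot`, `tree`, `year`, `h_ref` (dm, from
#'   [disc_height_age()] splines evaluated at the campaign age).
#' @return `measurements` plus `h_lev` and `lev_flag`, with a `"factors"`
#'   attribute of per-group multipliers.
#' @export
level_height_bias <- function(measurements, references) {
  m <- merge(measurements, references, by = c("plot", "tree", "year"),
             all.x = TRUE)
  grp <- interaction(measurements$plot, measurements$year, drop = TRUE)
  grp_m <- interaction(m$plot, m$year, drop = TRUE)
  fac <- tapply(seq_len(nrow(m)), grp_m, function(idx) {
    ok <- idx[!is.na(m$h_ref[idx]) & m$h[idx] > 0]
    if (!length(ok)) return(NA_real_)
    stats::median(m$h_ref[ok] / m$h[ok])
  })
  f <- as.vector(fac[as.character(grp)])
  flag <- is.na(f)
  f[flag] <- 1
  out <- measurements
  out$h_lev <- measurements$h * unname(f)
  out$lev_flag <- unname(flag)
  attr(out, "factors") <- data.frame(group = names(fac), factor = as.numeric(fac))
  out
}

height_age_formula <- function() {
  h ~ c0 * log(1 + exp(c2) * age^c3)^c1
}

#' Fit the height-age curve
#'
#' Nonlinear least squares for the four-parameter growth curve
#' `h = c0 * log(1 + exp(c2) * age^c3)^c1`, fitted to unbroken trees that
#' reached the final stand age. A small multi-start grid over plausible
#' shape parameters guards against local minima.
#'
#' @param age ages, years.
#' @param h heights, dm.
#' @return object of class `height_age_model` with elements `par`
#'   (c0, c1, c2, c3), `rss`, and `fit` (the underlying `nls` object).
#' @export
fit_height_age <- function(age, h) {
  ok <- is.finite(age) & is.finite(h) & age > 0
  age <- age[ok]; h <- h[ok]
  if (length(age) < 4L || length(unique(age)) < 3L)
    stop("need >= 4 (age, height) pairs over >= 3 distinct ages")
  dat <- data.frame(age = age, h = h)
  starts <- expand.grid(c1 = c(0.8, 1, 1.4), c2 = c(-4, -6, -8),
                        c3 = c(1.5, 2, 2.5))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    st <- as.list(starts[k, ])
    st$c0 <- max(h) / max(log(1 + exp(st$c2) * max(age)^st$c3)^st$c1, 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(height_age_formula(), data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("height-age fit did not converge from any start")
  par <- stats::coef(best$fit)[c("c0", "c1", "c2", "c3")]
  pr <- height_age_curve(par, sort(unique(age)))
  if (any(diff(pr) < -1e-8))
    warning("fitted height-age curve is not non-decreasing on the data range")
  structure(list(par = par, rss = best$rss, fit = best$fit),
            class = "height_age_model")
}

#' Evaluate the height-age curve at given parameters
#'
#' @param par named vector `c0`, `c1`, `c2`, `c3`.
#' @param age ages, years.
#' @return heights, dm.
#' @export
height_age_curve <- function(par, age) {
  unname(par["c0"] * log(1 + exp(par["c2"]) * age^par["c3"])^par["c1"])
}

#' @export
predict.height_age_model <- function(object, age, ...) {
  height_age_curve(object$par, age)
}

# largest admissible basis dimension for a smooth of x
term_k <- function(x, k) max(3L, min(k, length(unique(x)) - 1L))

# REML can fail on degenerate (noise-free) responses; fall back to GCV
fit_gam_safe <- function(form, dat) {
  g <- tryCatch(mgcv::gam(form, data = dat, method = "REML"),
                error = function(e) NULL)
  if (is.null(g))
    g <- tryCatch(mgcv::gam(form, data = dat, method = "GCV.Cp"),
                  error = function(e) NULL)
  if (is.null(g)) stop("penalized spline fit failed")
  g
}

re_factor <- function(tree, species, min_obs = 3L) {
  cnt <- table(tree)
  pooled <- names(cnt)[cnt < min_obs]
  f <- as.character(tree)
  f[f %in% pooled] <- paste0("sp:", species[f %in% pooled])
  factor(f)
}

#' Penalized-spline smoothing of the height ratio
#'
#' The ratio of the monotone levelled height to the height-age curve is
#' modelled as an additive penalized-spline function of age and diameter
#' (plus a spatial smooth over x, y when positions are supplied) with a
#' random intercept per tree; trees with fewer than `min_obs` observations
#' share a per-species intercept instead. Realized with [mgcv::gam()] and
#' `s(, bs = "re")`. Predictions are multiplied back by the curve and
#' isotonized per tree so smoothing never introduces a height decrease.
#'
#' @param obs data.frame with `tree`, `species`, `age`, `d`, `hMon` and
#'   optionally `x`, `y`.
#' @param newdata data.frame with `tree`, `species`, `age`, `d` (and `x`,
#'   `y` if used in `obs`) at every date to predict.
#' @param model a `height_age_model`.
#' @param use_xy include the spatial smooth (default: columns present).
#' @param k basis dimension per smooth (default 6).
#' @param min_obs threshold below which a tree falls back to the species
#'   intercept.
#' @return numeric vector `hSmooth` (dm) for the rows of `newdata`,
#'   non-decreasing within each tree (ordered by age).
#' @export
smooth_height <- function(obs, newdata, model,
                          use_xy = all(c("x", "y") %in% names(obs)),
                          k = 6, min_obs = 3L) {
  need <- c("tree", "species", "age", "d")
  for (col in c(need, if (use_xy) c("x", "y")))
    for (df_n in list(obs = obs, newdata = newdata))
      if (!col %in% names(df_n)) stop("missing covariate column: ", col)
  if (anyNA(newdata[c(need, if (use_xy) c("x", "y"))]))
    stop("missing covariate value in newdata")
  hfun <- height_age_curve(model$par, obs$age)
  dat <- obs
  dat$ratio <- obs$hMon / hfun
  dat$tree_f <- re_factor(dat$tree, dat$species, min_obs)
  ka <- term_k(dat$age, k); kd <- term_k(dat$d, k)
  kxy <- if (use_xy) max(4L, min(k, nrow(unique(dat[c("x", "y")])) - 1L)) else k
  form <- if (use_xy)
    ratio ~ s(age, k = ka) + s(d, k = kd) + s(x, y, k = kxy) + s(tree_f, bs = "re")
  else
    ratio ~ s(age, k = ka) + s(d, k = kd) + s(tree_f, bs = "re")
  g <- fit_gam_safe(form, dat)
  nd <- newdata
  nd$tree_f <- factor(ifelse(as.character(nd$tree) %in% levels(dat$tree_f),
                             as.character(nd$tree),
                             paste0("sp:", nd$species)),
                      levels = levels(dat$tree_f))
  # unseen levels (tree and species both absent from training): zero offset
  unseen <- is.na(nd$tree_f)
  if (any(unseen)) nd$tree_f[unseen] <- levels(dat$tree_f)[1]
  trm <- mgcv::predict.gam(g, newdata = nd, type = "terms")
  re_col <- grep("tree_f", colnames(trm))
  if (any(unseen) && length(re_col)) trm[unseen, re_col] <- 0
  pr <- as.numeric(attr(trm, "constant") + rowSums(trm))
  hS <- pr * height_age_curve(model$par, nd$age)
  for (tr in unique(nd$tree)) {
    idx <- which(nd$tree == tr)
    ord <- order(nd$age[idx])
    hS[idx[ord]] <- isotone_fit(nd$age[idx][ord], hS[idx[ord]])
  }
  hS
}

#' Anchor a smoothed series onto measured values
#'
#' At each observation date the multiplier `m = observed / smooth` is
#' computed; between observation dates `m` is interpolated linearly in
#' decimal years, and held constant before the first and after the last
#' anchor. The returned series reproduces every anchored observation
#' exactly.
#'
#' @param time decimal years of the full (smoothed) series.
#' @param smooth smoothed values, strictly positive.
#' @param anchor_time decimal years of the anchors (subset of `time` up to
#'   tolerance).
#' @param anchor_value monotone measured values at the anchors.
#' @return anchored series at `time`.
#' @export
anchor_to_observations <- function(time, smooth, anchor_time, anchor_value) {
  if (any(smooth <= 0)) stop("smoothed series must be strictly positive")
  if (!length(anchor_time)) return(smooth)
  s_at <- if (length(time) == 1L) rep(smooth, length(anchor_time))
          else stats::approx(time, smooth, xout = anchor_time, rule = 2)$y
  m <- anchor_value / s_at
  mt <- if (length(anchor_time) == 1L) rep(m, length(time))
        else stats::approx(anchor_time, m, xout = time, rule = 2)$y
  mt * smooth
}

#' Final monotonization of a height series with crown-break segments
#'
#' Isotonic projection applied independently within each segment between
#' recorded crown breaks (a decrease is allowed only across a break date);
#' interior flat runs are then replaced by placing the run value at the
#' run's mean date and interpolating linearly to the neighbouring values.
#'
#' @param time decimal years.
#' @param h heights, dm.
#' @param break_times decimal years at which a crown break was recorded; a
#'   break opens a new segment from the first `time >=` the break.
#' @return non-decreasing-per-segment heights, dm.
#' @export
finalize_heights <- function(time, h, break_times = numeric(0)) {
  n <- length(h)
  stopifnot(length(time) == n)
  seg <- findInterval(time, sort(break_times))
  out <- h
  for (s in unique(seg)) {
    idx <- which(seg == s)
    out[idx] <- interpolate_flat_runs_meandate(time[idx],
                                               isotone_fit(time[idx], h[idx]))
  }
  out
}
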