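#' Convert a calendar date to decimal years
#'
#' Measurement campaigns are unevenly spaced (1 to 6 years apart) and often
#' fall mid-season, so all increment arithmetic in the package runs on a
#' continuous time axis: year + day-of-year / 365.25.
#'
#' @param date a `Date` vector, or a character vector in `"YYYY-MM-DD"` form.
#' @return numeric vector of decimal years.
#' @export
#' @examples
#' decimal_year(as.Date("1950-07-01"))
decimal_year <- function(date) {
  if (is.character(date)) date <- as.Date(date)
  stopifnot(inherits(date, "Date"))
  yr <- as.integer(format(date, "%Y"))
  doy <- as.integer(format(date, "%j"))
  yr + doy / 365.25
}

#' Isotonic (monotone non-decreasing) least-squares projection
#'
#' Thin wrapper around [stats::isoreg()] returning the fitted values in the
#' order of `x`. `x` must be non-decreasing already (dates within one tree);
#' ties in `x` are allowed and share a fitted level.
#'
#' @param x ordinate (e.g. decimal year), non-decreasing.
#' @param y values to project.
#' @return numeric vector, non-decreasing, same length as `y`.
#' @export
isotone_fit <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  if (length(y) <= 1L) return(y)
  stats::isoreg(x, y)$yf
}

#' Replace interior flat runs by linear interpolation
#'
#' After isotonic projection a series can contain runs of equal values.
#' A maximal run with a strictly smaller predecessor and a strictly larger
#' successor carries no real signal about when the growth happened, so it is
#' replaced by the straight line (in time) between those two neighbours.
#' Runs touching the ends of the series, or runs without strict neighbours on
#' both sides, are left alone.
#'
#' @param x time axis (strictly increasing where it matters).
#' @param y non-decreasing values.
#' @return numeric vector, still non-decreasing.
#' @export
interpolate_flat_runs <- function(x, y) {
  n <- length(y)
  stopifnot(length(x) == n)
  if (n < 3L) return(y)
  out <- y
  i <- 2L
  while (i < n) {
    if (out[i] == out[i + 1L]) {
      j <- i
      while (j < n && out[j + 1L] == out[i]) j <- j + 1L
      # run is out[i..j]; neighbours out[i-1], out[j+1] (if present)
      if (i > 1L && j < n && out[i - 1L] < out[i] && out[j + 1L] > out[j]) {
        idx <- i:j
        out[idx] <- stats::approx(x = c(x[i - 1L], x[j + 1L]),
                                  y = c(out[i - 1L], out[j + 1L]),
                                  xout = x[idx])$y
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Replace flat runs using the run's mean date as an internal knot
#'
#' Variant used for final height and crown-base series: the run's common
#' value is deemed to have been attained at the run's mean date, and the
#' series is linearly interpolated from the previous observation through that
#' (mean date, value) knot to the next observation.
#'
#' @inheritParams interpolate_flat_runs
#' @return numeric vector, non-decreasing.
#' @export
interpolate_flat_runs_meandate <- function(x, y) {
  n <- length(y)
  stopifnot(length(x) == n)
  if (n < 3L) return(y)
  out <- y
  i <- 2L
  while (i < n) {
    if (out[i] == out[i + 1L]) {
      j <- i
      while (j < n && out[j + 1L] == out[i]) j <- j + 1L
      if (i > 1L && j < n && out[i - 1L] < out[i] && out[j + 1L] > out[j]) {
        idx <- i:j
        knots_x <- c(x[i - 1L], mean(x[idx]), x[j + 1L])
        knots_y <- c(out[i - 1L], out[i], out[j + 1L])
        out[idx] <- stats::approx(knots_x, knots_y, xout = x[idx])$y
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Monotone cubic Hermite (Fritsch-Carlson) interpolation
#'
#' Cubic Hermite interpolation whose knot tangents are limited by the
#' Fritsch-Carlson criterion (tangent/secant ratios projected onto the
#' circle of radius 3), which guarantees that monotone data yield a monotone
#' interpolant; the curve passes exactly through the knots. Tangents are
#' initialized from the secant means and zeroed at local extrema.
#' Extrapolation outside the knot range is refused: the pipeline only fills
#' interior observation gaps.
#'
#' @param x knot ordinates, strictly increasing.
#' @param y knot values.
#' @param xout query points, all within `range(x)`.
#' @return interpolated values at `xout`.
#' @export
monotone_interp <- function(x, y, xout) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L)
  if (is.unsorted(x, strictly = TRUE))
    stop("knot ordinates must be strictly increasing")
  if (any(xout < min(x) - 1e-9 | xout > max(x) + 1e-9))
    stop("extrapolation requested: only interior gaps can be filled")
  h <- diff(x)
  delta <- diff(y) / h
  m <- numeric(n)
  m[1] <- delta[1]; m[n] <- delta[n - 1L]
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      m[i] <- if (delta[i - 1L] * delta[i] <= 0) 0
              else (delta[i - 1L] + delta[i]) / 2
    }
  }
  for (i in seq_len(n - 1L)) {
    if (delta[i] == 0) {
      m[i] <- 0; m[i + 1L] <- 0
    } else {
      a <- m[i] / delta[i]; b <- m[i + 1L] / delta[i]
      r2 <- a^2 + b^2
      if (r2 > 9) {
        tau <- 3 / sqrt(r2)
        m[i] <- tau * a * delta[i]
        m[i + 1L] <- tau * b * delta[i]
      }
    }
  }
  xq <- pmin(pmax(xout, x[1]), x[n])
  k <- pmin(pmax(findInterval(xq, x), 1L), n - 1L)
  t <- (xq - x[k]) / h[k]
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[k] + h10 * h[k] * m[k] + h01 * y[k + 1L] + h11 * h[k] * m[k + 1L]
}

# basal area (mm^2) from diameter (mm); inverse
ba_from_d <- function(d) pi * (d / 2)^2
d_from_ba <- function(ba) 2 * sqrt(ba / pi)
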