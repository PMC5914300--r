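#' Decode a punch-card angle field
#'
#' Legacy height campaigns recorded clinometer angles on punch cards in a
#' fixed 3-character format: the angle in decimal degrees times ten, e.g.
#' `"123"` is 12.3 degrees. Downslope (negative) angles were coded by setting
#' the first digit to 9, with the remaining two digits carrying |angle| * 10:
#' `"903"` is -0.3 degrees.
#'
#' @param raw character vector of 3-digit strings.
#' @return numeric vector of signed angles in degrees.
#' @export
#' @examples
#' decode_angle(c("123", "903", "000"))
decode_angle <- function(raw) {
  raw <- as.character(raw)
  if (any(nchar(raw) != 3L | !grepl("^[0-9]{3}$", raw)))
    stop("angle fields must be exactly 3 digits")
  first <- substr(raw, 1L, 1L)
  ifelse(first == "9",
         -as.numeric(substr(raw, 2L, 3L)) / 10,
         as.numeric(raw) / 10)
}

check_angles <- function(...) {
  for (a in list(...))
    if (any(abs(a) >= 90)) stop("angles must lie strictly within (-90, 90) degrees")
  invisible(NULL)
}

#' Tree height from a base-bar hypsometer record
#'
#' Height triangulation for campaigns that measured the apparent length of a
#' bar of known size on the stem (variable observer distance recovered
#' optically): H = A * C * cos^2(WU) * (tan(WO) + tan(WU)) + K.
#'
#' @param A apparent base-bar length in cm.
#' @param WO angle to the tree top, degrees.
#' @param WU angle to the measurement mark on the stem, degrees (downslope
#'   negative).
#' @param C device constant, dimensionless; default 1/0.3.
#' @param K height of the measurement mark above ground in dm; default 13.
#' @return tree height in dm.
#' @export
#' @examples
#' height_base_bar(A = 30, WO = 45, WU = 0)  # 113 dm
height_base_bar <- function(A, WO, WU, C = 1 / 0.3, K = 13) {
  stopifnot(all(A > 0), all(K >= 0))
  check_angles(WO, WU)
  wo <- WO * pi / 180; wu <- WU * pi / 180
  A * C * cos(wu)^2 * (tan(wo) + tan(wu)) + K
}

#' Tree height from a slope-distance hypsometer record
#'
#' Triangulation for campaigns that measured the slope distance from the
#' observer to a mark on the stem: H = D * cos(WU) * (tan(WO) + tan(WU)) + K.
#'
#' @param D slope distance observer-to-mark in dm.
#' @inheritParams height_base_bar
#' @return tree height in dm.
#' @export
#' @examples
#' height_slope_distance(D = 100, WO = 45, WU = 0)  # 113 dm
height_slope_distance <- function(D, WO, WU, K = 13) {
  stopifnot(all(D > 0), all(K >= 0))
  check_angles(WO, WU)
  wo <- WO * pi / 180; wu <- WU * pi / 180
  D * cos(wu) * (tan(wo) + tan(wu)) + K
}
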