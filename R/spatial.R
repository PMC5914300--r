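## Planting-raster reconstruction. Trees were planted on a rectangular grid;
## stem positions were only mapped decades later, so the grid (origin,
## spacing in the two row directions, and a small orientation angle of the
## mapped coordinate frame) is recovered from the surviving stems by
## alternating nearest-node assignment and least-squares refit -- a
## grid-constrained ICP. Assignment uses the current affine estimate; the
## refit is a plain linear regression of position on integer node indices.

affine_from_fit <- function(o, u, v) {
  list(o = o, A = cbind(u, v))
}

#' Fit a planting raster to mapped stem positions
#'
#' Estimates origin, spacing in both planting directions, and a small
#' orientation angle by minimizing the sum of squared distances between each
#' mapped position and its nearest raster node. Assignment of positions to
#' nodes and the least-squares update alternate until the assignment is
#' stable.
#'
#' @param positions data.frame or matrix with columns `x`, `y` (m).
#' @param spacing numeric length-2, initial spacing guess (m) in x and y.
#' @param max_iter maximum assignment/update rounds per start.
#' @details The alternating assignment/refit scheme can lock onto a wrong
#'   lattice when the initial spacing is off by several percent, so the fit
#'   is restarted from a small grid of spacing scale factors around the
#'   guess and the solution with the smallest rms residual is kept.
#' @return object of class `raster_fit`: list with `origin`, `spacing_x`,
#'   `spacing_y`, `orientation` (radians), `rms_residual` (m), `nodes`
#'   (integer node index per input position) and the affine node->plane map.
#' @export
fit_raster <- function(positions, spacing, max_iter = 100L) {
  xy <- as.matrix(as.data.frame(positions)[, c("x", "y")])
  n <- nrow(xy)
  if (n < 4L) stop("at least 4 positions are required")
  sv <- svd(scale(xy, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) stop("positions are collinear")
  stopifnot(length(spacing) == 2L, all(spacing > 0))

  o0 <- xy[which.min(xy[, 1] + xy[, 2]), ]
  best <- NULL
  scales <- c(1, 0.9, 0.95, 1.05, 1.1)
  for (fx in scales) for (fy in scales) {
    cand <- fit_raster_once(xy, o0, diag(spacing * c(fx, fy)), max_iter)
    if (is.null(cand)) next
    if (is.null(best) || cand$rms_residual < best$rms_residual) best <- cand
    if (best$rms_residual < 1e-10) break
  }
  if (is.null(best))
    stop("raster fit did not converge: degenerate node assignment")
  best
}

fit_raster_once <- function(xy, o, A, max_iter) {
  n <- nrow(xy)
  ij_old <- NULL
  for (iter in seq_len(max_iter)) {
    g <- tryCatch(t(solve(A, t(xy) - o)), error = function(e) NULL)
    if (is.null(g)) return(NULL)
    ij <- round(g)
    if (!is.null(ij_old) && identical(ij, ij_old)) break
    ij_old <- ij
    # least-squares refit of o, A given the assignment
    X <- cbind(1, ij)
    if (qr(X)$rank < 3L) return(NULL)
    cf <- qr.solve(X, xy)          # rows: intercept, i, j; cols: x, y
    o <- cf[1, ]
    A <- t(cf[2:3, , drop = FALSE])
  }
  # normalize the node frame: axes point along +x/+y, lower-left occupied
  # node gets index (0, 0)
  if (A[1, 1] < 0) { A[, 1] <- -A[, 1]; ij[, 1] <- -ij[, 1] }
  if (A[2, 2] < 0) { A[, 2] <- -A[, 2]; ij[, 2] <- -ij[, 2] }
  shift <- apply(ij, 2, min)
  o <- as.numeric(o + A %*% shift)
  ij <- sweep(ij, 2, shift)
  res <- xy - (rep(1, n) %o% o + ij %*% t(A))
  u <- A[, 1]; v <- A[, 2]
  structure(list(
    origin = unname(o),
    spacing_x = sqrt(sum(u^2)),
    spacing_y = sqrt(sum(v^2)),
    orientation = atan2(u[2], u[1]),
    rms_residual = sqrt(mean(rowSums(res^2))),
    nodes = unname(ij),
    affine = list(o = unname(o), A = unname(A))
  ), class = "raster_fit")
}

#' @export
print.raster_fit <- function(x, ...) {
  cat(sprintf("Planting raster: spacing %.3f m x %.3f m, orientation %.2f deg, rms residual %.3f m\n",
              x$spacing_x, x$spacing_y, x$orientation * 180 / pi, x$rms_residual))
  invisible(x)
}

raster_node_xy <- function(fit, ij) {
  ij <- as.matrix(ij)
  rep(1, nrow(ij)) %o% fit$affine$o + ij %*% t(fit$affine$A)
}

#' Node implied by a tree number under serpentine numbering
#'
#' Trees were numbered along the planting rows, with the walking direction
#' alternating row by row (boustrophedon). Number `k` (1-based, after
#' subtracting `offset`) maps to row `(k-1) %/% n_cols + 1` and a column that
#' runs forward on odd rows and backward on even rows.
#'
#' @param number integer tree number(s).
#' @param n_cols trees per row.
#' @param offset first tree number minus one.
#' @param serpentine alternate direction on even rows (default `TRUE`).
#' @return matrix with columns `i` (column index) and `j` (row index),
#'   zero-based, suitable for [fit_raster()] node coordinates.
#' @export
serpentine_node <- function(number, n_cols, offset = 0L, serpentine = TRUE) {
  k <- number - offset - 1L
  row <- k %/% n_cols
  posr <- k %% n_cols
  col <- if (serpentine) ifelse(row %% 2L == 1L, n_cols - 1L - posr, posr) else posr
  cbind(i = col, j = row)
}

#' Place trees removed before the mapping campaign on raster nodes
#'
#' Trees removed before positions were mapped have no coordinates. Those
#' whose numbers fit the serpentine numbering pattern are placed on their
#' implied node if it is vacant; the rest are placed uniformly at random
#' (seeded) on the remaining vacant nodes. No node is used twice.
#'
#' @param numbers integer vector of tree numbers to place.
#' @param fit a `raster_fit`.
#' @param extent integer length-2: number of columns and rows of the raster.
#' @param occupied integer matrix of (i, j) node indices already taken by
#'   mapped trees (e.g. `fit$nodes`).
#' @param numbering list with `n_cols`, `offset`, `serpentine`; see
#'   [serpentine_node()].
#' @param seed integer seed for the random placement of out-of-pattern trees.
#' @return data.frame with `tree`, `i`, `j`, `x`, `y`, `posObs` (always
#'   `FALSE`) and `matched` (`TRUE` when placed via the numbering model).
#' @export
estimate_removed_positions <- function(numbers, fit, extent, occupied,
                                       numbering, seed = 1L) {
  all_nodes <- expand.grid(i = 0:(extent[1] - 1L), j = 0:(extent[2] - 1L))
  node_id <- function(ij) ij[, 1] + ij[, 2] * extent[1]
  occ <- unique(node_id(as.matrix(occupied)))
  vacant <- setdiff(node_id(as.matrix(all_nodes)), occ)
  if (length(numbers) > length(vacant))
    stop("more removed trees (", length(numbers), ") than vacant nodes (",
         length(vacant), ")")
  pred <- serpentine_node(numbers, numbering$n_cols,
                          offset = numbering$offset %||% 0L,
                          serpentine = numbering$serpentine %||% TRUE)
  pid <- node_id(pred)
  in_extent <- pred[, 1] >= 0 & pred[, 1] < extent[1] &
               pred[, 2] >= 0 & pred[, 2] < extent[2]
  matched <- logical(length(numbers))
  assigned <- rep(NA_real_, length(numbers))
  taken <- integer(0)
  for (k in order(numbers)) {
    if (in_extent[k] && pid[k] %in% vacant && !(pid[k] %in% taken)) {
      assigned[k] <- pid[k]; taken <- c(taken, pid[k]); matched[k] <- TRUE
    }
  }
  rest <- which(!matched)
  if (length(rest)) {
    pool <- setdiff(vacant, taken)
    set.seed(seed)
    pick <- if (length(rest) == 1L) sample(pool, 1L) else sample(pool, length(rest))
    assigned[rest] <- pick
  }
  ij <- cbind(i = assigned %% extent[1], j = assigned %/% extent[1])
  xy <- raster_node_xy(fit, ij)
  data.frame(tree = numbers, i = ij[, 1], j = ij[, 2],
             x = xy[, 1], y = xy[, 2], posObs = FALSE, matched = matched)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Snap plot corners to mid-row positions and compute the plot area
#'
#' Plot borders run exactly between the planting rows. A measured corner
#' that is not aligned mid-way between rows in both raster directions is
#' replaced by the nearest point whose raster coordinates are half-integers;
#' the polygon area of the adjusted corners is computed by the shoelace
#' formula.
#'
#' @param corners data.frame with columns `x`, `y` (m), in polygon order.
#' @param fit a `raster_fit`.
#' @param tol displacement (m) below which a corner counts as already
#'   mid-row.
#' @return list with `corners` (data.frame `x`, `y`, `cor` — `TRUE` where
#'   the corner was moved) and `area` in m².
#' @export
correct_corners <- function(corners, fit, tol = 1e-6) {
  xy <- as.matrix(as.data.frame(corners)[, c("x", "y")])
  if (nrow(xy) != 4L) stop("exactly 4 corners expected")
  g <- t(solve(fit$affine$A, t(xy) - fit$affine$o))
  snapped_g <- round(g - 0.5) + 0.5      # nearest half-integer per axis
  snapped <- raster_node_xy(fit, snapped_g)
  moved <- sqrt(rowSums((snapped - xy)^2)) > tol
  out <- ifelse(matrix(moved, nrow(xy), 2L), snapped, xy)
  area <- shoelace_area(out[, 1], out[, 2])
  if (area < 1e-9) stop("degenerate corner polygon")
  list(corners = data.frame(x = out[, 1], y = out[, 2], cor = moved),
       area = area)
}

#' Point-in-polygon test (ray casting)
#'
#' Used to restrict stand summaries to trees inside the corrected plot
#' border. Points on an edge count as inside.
#'
#' @param px,py point coordinates.
#' @param polyx,poly_y polygon vertex coordinates in order.
#' @param poly_y polygon y vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, polyx, poly_y) {
  n <- length(polyx)
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]; flag <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- polyx[i]; yi <- poly_y[i]; xj <- polyx[j]; yj <- poly_y[j]
      # on-edge check
      if (abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi)) < 1e-9 &&
          x >= min(xi, xj) - 1e-9 && x <= max(xi, xj) + 1e-9 &&
          y >= min(yi, yj) - 1e-9 && y <= max(yi, yj) + 1e-9) {
        flag <- TRUE; break
      }
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) flag <- !flag
      j <- i
    }
    inside[k] <- flag
  }
  inside
}
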