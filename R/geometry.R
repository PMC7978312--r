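# Geometry in the micrometre image frame.
#
# One coordinate convention is used package-wide: pixel [row, col] (1-based)
# has its centre at x = (col - 0.5) * pixel_size, y = (row - 0.5) * pixel_size,
# with x increasing along columns and y increasing down rows.

#' Pixel-centre coordinates in micrometres
#'
#' @param rows,cols integer vectors of 1-based pixel indices (recycled).
#' @param pixel_size calibration in um/pixel.
#' @return two-column matrix with columns `x`, `y` (um).
#' @keywords internal
pixel_centers_um <- function(rows, cols, pixel_size) {
  cbind(x = (cols - 0.5) * pixel_size, y = (rows - 0.5) * pixel_size)
}

#' Arc length of a polyline
#'
#' @param xy two-column matrix of vertices (um).
#' @return total length in um (0 for fewer than 2 vertices).
#' @keywords internal
polyline_length <- function(xy) {
  if (is.null(xy) || nrow(xy) < 2) return(0)
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}

# Minimum distance from each point to one segment (p1 -> p2), vectorized
# over points.
.dist_points_segment <- function(px, py, p1, p2) {
  dx <- p2[1] - p1[1]
  dy <- p2[2] - p1[2]
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    return(sqrt((px - p1[1])^2 + (py - p1[2])^2))
  }
  t <- ((px - p1[1]) * dx + (py - p1[2]) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (p1[1] + t * dx))^2 + (py - (p1[2] + t * dy))^2)
}

#' Minimum distance from points to a polyline
#'
#' @param pts two-column matrix of points (um).
#' @param poly two-column matrix of polyline vertices (um); a single vertex is
#'   treated as a point.
#' @return numeric vector of distances (um).
#' @keywords internal
dist_points_polyline <- function(pts, poly) {
  px <- pts[, 1]
  py <- pts[, 2]
  if (nrow(poly) == 1) {
    return(sqrt((px - poly[1, 1])^2 + (py - poly[1, 2])^2))
  }
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(poly) - 1)) {
    d <- pmin(d, .dist_points_segment(px, py, poly[i, ], poly[i + 1, ]))
  }
  d
}

#' Minimum distance from points to a set of process traces
#'
#' @param pts two-column matrix of points (um).
#' @param traces a [process_traces] object (its polylines are used; a
#'   mask-only trace set falls back to mask pixel centres).
#' @return list with `distance` (um, `Inf` when there are no traces) and
#'   `process_id` (index of the nearest polyline, `NA` when none).
#' @keywords internal
dist_points_traces <- function(pts, traces) {
  n <- nrow(pts)
  if (length(traces$polylines) == 0) {
    if (!is.null(traces$mask) && any(traces$mask)) {
      idx <- which(traces$mask, arr.ind = TRUE)
      ctr <- pixel_centers_um(idx[, 1], idx[, 2], traces$pixel_size)
      d <- rep(Inf, n)
      for (k in seq_len(nrow(ctr))) {
        d <- pmin(d, sqrt((pts[, 1] - ctr[k, 1])^2 + (pts[, 2] - ctr[k, 2])^2))
      }
      return(list(distance = d, process_id = ifelse(is.finite(d), 1L, NA_integer_)))
    }
    return(list(distance = rep(Inf, n), process_id = rep(NA_integer_, n)))
  }
  best <- rep(Inf, n)
  best_id <- rep(NA_integer_, n)
  for (i in seq_along(traces$polylines)) {
    di <- dist_points_polyline(pts, traces$polylines[[i]])
    upd <- di < best
    best[upd] <- di[upd]
    best_id[upd] <- i
  }
  list(distance = best, process_id = best_id)
}

#' Sample a polyline at regular arc-length steps
#'
#' @param poly two-column vertex matrix (um).
#' @param step arc-length step (um).
#' @return list with `s` (arc-length positions, starting at 0 and covering the
#'   full length), `x`, `y` (interpolated coordinates).
#' @keywords internal
sample_polyline <- function(poly, step) {
  stopifnot(step > 0, nrow(poly) >= 2)
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  x <- stats::approx(cum, poly[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, poly[, 2], xout = s, ties = "ordered")$y
  list(s = s, x = x, y = y)
}

#' Interpolate point positions along a polyline at given arc lengths
#'
#' @keywords internal
point_at_arclength <- function(poly, s) {
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  cbind(
    x = stats::approx(cum, poly[, 1], xout = s, ties = "ordered")$y,
    y = stats::approx(cum, poly[, 2], xout = s, ties = "ordered")$y
  )
}

#' Bilinear interpolation of an intensity grid at micrometre coordinates
#'
#' Interpolates between pixel centres; coordinates beyond the outermost
#' centres are clamped to the border value.
#'
#' @param pixels numeric matrix (rows = y, cols = x).
#' @param x,y coordinates in um.
#' @param pixel_size calibration in um/pixel.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_interp <- function(pixels, x, y, pixel_size) {
  nr <- nrow(pixels)
  nc <- ncol(pixels)
  # continuous pixel coordinates such that integer values sit on centres
  cx <- x / pixel_size + 0.5
  cy <- y / pixel_size + 0.5
  cx <- pmin(pmax(cx, 1), nc)
  cy <- pmin(pmax(cy, 1), nr)
  c0 <- pmin(floor(cx), nc - 1L); c0 <- pmax(c0, 1L)
  r0 <- pmin(floor(cy), nr - 1L); r0 <- pmax(r0, 1L)
  fx <- cx - c0
  fy <- cy - r0
  if (nc == 1) { c0 <- rep(1L, length(cx)); fx <- 0 }
  if (nr == 1) { r0 <- rep(1L, length(cy)); fy <- 0 }
  i00 <- pixels[cbind(r0, c0)]
  i01 <- pixels[cbind(r0, pmin(c0 + 1L, nc))]
  i10 <- pixels[cbind(pmin(r0 + 1L, nr), c0)]
  i11 <- pixels[cbind(pmin(r0 + 1L, nr), pmin(c0 + 1L, nc))]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}
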