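# Planar polygon primitives used by the grid module.
#
# Grid cells are axis-aligned rectangles, so the only overlay operation the
# pipeline ever needs is "polygon clipped by a rectangle".  That is the
# textbook Sutherland-Hodgman case (the clip window is convex), and doing it
# exactly here avoids depending on a full geometry engine.

#' Signed area of a polygon ring (shoelace formula)
#'
#' @param ring two-column numeric matrix of vertices (x, y); the ring may be
#'   open or explicitly closed.
#' @return signed area; positive for counter-clockwise rings.
#' @keywords internal
ring_area_signed <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]; y <- y[-n]
    n <- n - 1L
    if (n < 3L) return(0)
  }
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Absolute polygon area, summed over rings of a multipolygon
#'
#' Rings are simple polygons without holes; a list is treated as a
#' multipolygon whose parts have disjoint interiors.
#' @param poly a ring matrix or a list of ring matrices.
#' @keywords internal
polygon_area <- function(poly) {
  if (is.list(poly)) return(sum(vapply(poly, polygon_area, numeric(1))))
  abs(ring_area_signed(poly))
}

# Clip one ring against a half-plane keep(x, y) >= 0 with linear boundary;
# `edge` is c(a, b, c) meaning keep a*x + b*y + c >= 0.
clip_ring_halfplane <- function(ring, edge) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  if (ring[1L, 1L] == ring[n, 1L] && ring[1L, 2L] == ring[n, 2L]) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n == 0L) return(ring)
  val <- edge[1L] * ring[, 1L] + edge[2L] * ring[, 2L] + edge[3L]
  out_x <- numeric(2L * n)
  out_y <- numeric(2L * n)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi >= 0) {
      m <- m + 1L
      out_x[m] <- ring[i, 1L]; out_y[m] <- ring[i, 2L]
    }
    if ((vi >= 0) != (vj >= 0)) {
      t <- vi / (vi - vj)
      m <- m + 1L
      out_x[m] <- ring[i, 1L] + t * (ring[j, 1L] - ring[i, 1L])
      out_y[m] <- ring[i, 2L] + t * (ring[j, 2L] - ring[i, 2L])
    }
  }
  cbind(out_x[seq_len(m)], out_y[seq_len(m)])
}

#' Clip a polygon against an axis-aligned rectangle
#'
#' @param poly ring matrix or list of ring matrices (multipolygon).
#' @param x0,y0,x1,y1 rectangle bounds, `x0 < x1`, `y0 < y1`.
#' @return clipped polygon in the same form (list in, list out).
#' @keywords internal
clip_polygon_rect <- function(poly, x0, y0, x1, y1) {
  if (is.list(poly)) {
    return(lapply(poly, clip_polygon_rect, x0 = x0, y0 = y0, x1 = x1, y1 = y1))
  }
  edges <- list(
    c(1, 0, -x0),   #  x >= x0
    c(-1, 0, x1),   #  x <= x1
    c(0, 1, -y0),   #  y >= y0
    c(0, -1, y1)    #  y <= y1
  )
  ring <- poly
  for (e in edges) {
    ring <- clip_ring_halfplane(ring, e)
    if (nrow(ring) < 3L) return(matrix(numeric(0), ncol = 2L))
  }
  ring
}

#' Validate a polygon argument
#'
#' @keywords internal
check_polygon <- function(poly, what = "polygon") {
  rings <- if (is.list(poly)) poly else list(poly)
  if (length(rings) == 0L) stop(what, " is empty", call. = FALSE)
  for (r in rings) {
    if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L || !all(is.finite(r))) {
      stop(what, " must be one or more two-column numeric matrices with >= 3 finite vertices",
           call. = FALSE)
    }
  }
  invisible(poly)
}
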