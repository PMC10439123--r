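# The 10 x 10 km cartogram grid: construction, point-to-square assignment,
# and cross-boundary flagging against a territory polygon.

#' Define a square cartogram grid
#'
#' The grid tiles the plane with `n_rows * n_cols` square cells of side
#' `cell_size` metres, anchored at the lower-left corner
#' `(origin_x, origin_y)` of cell (row 0, col 0).  Rows increase northward,
#' columns eastward.  Cells are half-open, closed on their lower-left edges,
#' so every point belongs to at most one cell.
#'
#' Square codes follow the two-level convention of classical cartogram
#' atlases: a pair of letters naming the 100-km block, followed by the
#' row and column digit within the block (e.g. `"BC27"`).  Codes are
#' treated as opaque keys everywhere downstream; geometry is never
#' re-derived from a code.
#'
#' @param origin_x,origin_y planar coordinates (m) of the grid anchor.
#' @param cell_size cell side length in metres (default 10000 = 10 km).
#' @param n_rows,n_cols grid dimensions; each must be >= 1 (and <= 260,
#'   the capacity of the letter-pair/digit-pair code scheme).
#' @param crs local planar reference system created by [local_crs()]; used
#'   to convert plot longitude/latitude to grid coordinates and back.
#' @return an object of class `grid_spec`.
#' @seealso [build_grid()], [assign_point()]
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, cell_size = 10000,
                      n_rows, n_cols, crs = local_crs()) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("cell_size must be a positive finite number", call. = FALSE)
  }
  for (v in list(n_rows, n_cols)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 || v != round(v)) {
      stop("n_rows and n_cols must be positive integers", call. = FALSE)
    }
  }
  if (n_rows > 260 || n_cols > 260) {
    stop("the letter-pair code scheme supports at most 260 rows/columns", call. = FALSE)
  }
  if (!all(is.finite(c(origin_x, origin_y)))) {
    stop("origin coordinates must be finite", call. = FALSE)
  }
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols), crs = crs),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g km, anchor (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size / 1000, x$origin_x, x$origin_y))
  invisible(x)
}

#' A simple local planar reference system
#'
#' An equirectangular projection about a reference point: metres east/north
#' of (`lon0`, `lat0`) with the metre-per-degree scale fixed at the
#' reference latitude.  Adequate for a synthetic country-sized territory;
#' real atlas grids come with their own georeferencing, which this package
#' treats as out of scope (square codes are opaque keys).
#'
#' @param lon0,lat0 reference longitude/latitude in decimal degrees.
#' @return an object of class `local_crs`.
#' @export
local_crs <- function(lon0 = 19, lat0 = 52) {
  m_per_deg_lat <- 111320
  structure(list(lon0 = lon0, lat0 = lat0,
                 mx = m_per_deg_lat * cos(lat0 * pi / 180),
                 my = m_per_deg_lat),
            class = "local_crs")
}

#' Project geographic coordinates to the local planar system
#'
#' @param lon,lat numeric vectors, decimal degrees (EPSG 4326 axis order
#'   longitude, latitude).
#' @param crs a [local_crs()].
#' @return data.frame with columns `x`, `y` in metres.
#' @export
lonlat_to_planar <- function(lon, lat, crs) {
  stopifnot(inherits(crs, "local_crs"))
  data.frame(x = (lon - crs$lon0) * crs$mx, y = (lat - crs$lat0) * crs$my)
}

#' Inverse of [lonlat_to_planar()]
#'
#' @param x,y planar coordinates in metres.
#' @param crs a [local_crs()].
#' @return data.frame with columns `lon`, `lat`.
#' @export
planar_to_lonlat <- function(x, y, crs) {
  stopifnot(inherits(crs, "local_crs"))
  data.frame(lon = crs$lon0 + x / crs$mx, lat = crs$lat0 + y / crs$my)
}

# "BC27" style code from 0-based row/col: letters name the 100-km block
# (10-cell blocks), digits the cell within the block.
square_code <- function(row, col) {
  paste0(LETTERS[row %/% 10L + 1L], LETTERS[col %/% 10L + 1L],
         row %% 10L, col %% 10L)
}

#' Build the square grid
#'
#' @param spec a [grid_spec()].
#' @return data.frame of class `flora_grid` with one row per square:
#'   `square_id`, 0-based `row`/`col`, and cell bounds `x0, y0, x1, y1`
#'   (planar metres).  The `spec` is attached as an attribute.
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  row <- rep(seq_len(spec$n_rows) - 1L, each = spec$n_cols)
  col <- rep(seq_len(spec$n_cols) - 1L, times = spec$n_rows)
  g <- data.frame(
    square_id = square_code(row, col),
    row = row, col = col,
    x0 = spec$origin_x + col * spec$cell_size,
    y0 = spec$origin_y + row * spec$cell_size,
    stringsAsFactors = FALSE
  )
  g$x1 <- g$x0 + spec$cell_size
  g$y1 <- g$y0 + spec$cell_size
  stopifnot(!anyDuplicated(g$square_id))
  attr(g, "spec") <- spec
  class(g) <- c("flora_grid", "data.frame")
  g
}

#' Assign planar points to grid squares
#'
#' Cells are half-open, `[x0, x0 + cell) x [y0, y0 + cell)`: a point on a
#' shared edge belongs to the cell whose lower-left corner it is nearest in
#' the closed direction, so counts are conserved.
#'
#' @param x,y numeric vectors of planar coordinates (metres).  Geographic
#'   coordinates must be projected with [lonlat_to_planar()] first.
#' @param spec a [grid_spec()].
#' @return character vector of square codes, `NA` for points outside the
#'   grid extent.
#' @export
assign_point <- function(x, y, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  col <- floor((x - spec$origin_x) / spec$cell_size)
  row <- floor((y - spec$origin_y) / spec$cell_size)
  inside <- row >= 0 & row < spec$n_rows & col >= 0 & col < spec$n_cols
  out <- rep(NA_character_, length(x))
  out[inside] <- square_code(as.integer(row[inside]), as.integer(col[inside]))
  out
}

#' Fraction of a square's area inside a territory polygon
#'
#' @param square one row of a [build_grid()] result (or any list with
#'   `x0, y0, x1, y1`).
#' @param territory a ring matrix or list of ring matrices in the same
#'   planar system.
#' @return area(square intersect territory) / area(square), in `[0, 1]`.
#' @export
inside_fraction <- function(square, territory) {
  check_polygon(territory, "territory")
  cell_area <- (square$x1 - square$x0) * (square$y1 - square$y0)
  if (!is.finite(cell_area) || cell_area <= 0) {
    stop("square has invalid extent", call. = FALSE)
  }
  clipped <- clip_polygon_rect(territory, square$x0, square$y0, square$x1, square$y1)
  frac <- polygon_area(clipped) / cell_area
  min(max(frac, 0), 1)
}

#' Cross-boundary flag from an inside-area fraction
#'
#' A square is kept (flag 1) only when *more than* `threshold` of its area
#' lies inside the territory; the comparison is strict, so a square at
#' exactly 80% is flagged 0.
#'
#' @param fraction numeric vector in `[0, 1]`.
#' @param threshold default 0.80.
#' @return integer vector of 0/1 flags.
#' @export
flag_cross_boundary <- function(fraction, threshold = 0.80) {
  if (!all(is.finite(fraction)) || any(fraction < 0 | fraction > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  as.integer(fraction > threshold)
}

#' Compute inside fractions and cross-boundary flags for a whole grid
#'
#' @param grid a [build_grid()] result.
#' @param territory polygon (ring matrix or list of rings) in the grid's
#'   planar system.
#' @param threshold passed to [flag_cross_boundary()].
#' @return data.frame `square_id`, `inside_fraction`, `CBS`.
#' @export
grid_cbs <- function(grid, territory, threshold = 0.80) {
  check_polygon(territory, "territory")
  frac <- vapply(seq_len(nrow(grid)), function(i) {
    inside_fraction(grid[i, , drop = FALSE], territory)
  }, numeric(1))
  data.frame(square_id = grid$square_id,
             inside_fraction = frac,
             CBS = flag_cross_boundary(frac, threshold),
             stringsAsFactors = FALSE)
}

#' Corner polygon of one grid square
#'
#' @keywords internal
square_ring <- function(square) {
  cbind(c(square$x0, square$x1, square$x1, square$x0, square$x0),
        c(square$y0, square$y0, square$y1, square$y1, square$y0))
}
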