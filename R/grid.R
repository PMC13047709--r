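#' Grid geometry of a raster layer
#'
#' A `grid_spec` describes the geometry shared by every layer of an
#' environmental stack: the matrix dimensions, the map coordinates of the
#' lower-left corner, the (square) cell size, and the nodata sentinel.
#' Cell `(1, 1)` of the value matrix is the top-left (most northerly) cell,
#' matching the row order of ESRI ASCII grids.
#'
#' @param n_rows,n_cols Positive integers, the matrix dimensions.
#' @param x_origin,y_origin Map coordinates of the lower-left *corner* of the
#'   grid (degrees for geographic grids, map units otherwise).
#' @param cell_size Positive cell edge length (degrees or map units).
#' @param crs One of `"geographic"`, `"projected"`, `"abstract"`. Only used to
#'   pick sensible defaults (e.g. great-circle vs euclidean distances).
#' @param nodata Sentinel value written for invalid cells.
#'
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, x_origin = 0, y_origin = 0,
                      cell_size = 1, crs = c("abstract", "geographic", "projected"),
                      nodata = -9999) {
  crs <- match.arg(crs)
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
      cell_size = as.numeric(cell_size), crs = crs, nodata = as.numeric(nodata)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, origin (%g, %g), cell size %g, crs %s\n",
    x$n_rows, x$n_cols, x$x_origin, x$y_origin, x$cell_size, x$crs
  ))
  invisible(x)
}

#' Are two grid geometries aligned?
#'
#' Alignment means all six numeric geometry fields agree within an absolute
#' tolerance; operations that combine grids (stacking, change maps) require
#' it.
#'
#' @param a,b `grid_spec` objects.
#' @param tol Absolute tolerance on each numeric field.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  all(abs(c(
    a$n_rows - b$n_rows, a$n_cols - b$n_cols,
    a$x_origin - b$x_origin, a$y_origin - b$y_origin,
    a$cell_size - b$cell_size, a$nodata - b$nodata
  )) <= tol)
}

#' Cell-area model
#'
#' Areas feed every habitat accounting table. Two conventions are supported:
#' a constant per-cell area (the default for abstract/synthetic grids, where
#' 1 km2 cells make counts and areas interchangeable) and a latitude-cosine
#' model for geographic grids, where a cell spanning `cell_size` degrees has
#' area `(R * d)^2 * cos(lat_centre)` with `d` the cell size in radians.
#'
#' @param mode `"constant"` or `"latitude-cosine"`.
#' @param cell_area_km2 Constant per-cell area in km2 (constant mode).
#' @param earth_radius_km Earth radius in km (latitude-cosine mode).
#' @return An `area_model` object.
#' @export
area_model <- function(mode = c("constant", "latitude-cosine"),
                       cell_area_km2 = 1, earth_radius_km = 6371.0) {
  mode <- match.arg(mode)
  stopifnot(cell_area_km2 > 0, earth_radius_km > 0)
  structure(
    list(mode = mode, cell_area_km2 = cell_area_km2,
         earth_radius_km = earth_radius_km),
    class = "area_model"
  )
}

#' Per-row cell areas of a grid
#'
#' @param spec A `grid_spec`.
#' @param model An [area_model()]. In latitude-cosine mode the grid's y
#'   coordinates are interpreted as degrees latitude.
#' @return Numeric vector of length `n_rows` (row 1 = top row), cell area in
#'   km2 for each latitude band.
#' @export
cell_areas <- function(spec, model = area_model()) {
  if (model$mode == "constant") {
    return(rep(model$cell_area_km2, spec$n_rows))
  }
  lat <- row_centres(spec)
  if (any(abs(lat) >= 90)) {
    abort_sdm("row-centre latitude outside (-90, 90) in latitude-cosine mode",
              "sdmflow_domain_error")
  }
  d <- spec$cell_size * pi / 180
  (model$earth_radius_km * d)^2 * cos(lat * pi / 180)
}

# y (latitude) coordinate of each row centre, row 1 = top.
row_centres <- function(spec) {
  spec$y_origin + (spec$n_rows - seq_len(spec$n_rows) + 0.5) * spec$cell_size
}

# x (longitude) coordinate of each column centre.
col_centres <- function(spec) {
  spec$x_origin + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
}

# Map a set of points to (row, col) indices under the half-open cell
# convention: a point belongs to the cell whose [left, right) x interval and
# [bottom, top) y interval contain it. Returns NA indices for points outside
# the grid extent.
point_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$x_origin) / spec$cell_size) + 1
  row_from_bottom <- floor((y - spec$y_origin) / spec$cell_size)
  row <- spec$n_rows - row_from_bottom
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col), out_of_bounds = bad)
}
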