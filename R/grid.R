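#' Georeferenced regular grid
#'
#' A `grid_spec` fixes the lattice every raster layer lives on: a CRS, the
#' coordinates of the top-left corner of the top-left cell, a square cell
#' size, and the number of rows and columns. Row indices increase southward;
#' extents are half-open `[min, max)`. Cell centers sit at
#' `origin + (index - 0.5) * cell_size`.
#'
#' Kilometer-lattice products (metric levels) use cell sizes that are integer
#' multiples or integer submultiples of 1000 m, so that layers of different
#' resolution share cell boundaries once snapped to the master grid.
#'
#' @param crs CRS identifier, `"EPSG:32632"` (UTM zone 32N, meters) or
#'   `"EPSG:4326"` (WGS84, degrees).
#' @param origin_x,origin_y Coordinates of the top-left corner of the
#'   top-left cell, in CRS units.
#' @param cell_size Cell edge length in CRS units; must be positive.
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec("EPSG:32632", 600000, 5100000, 1000, 10, 10)
#' grid_extent(g)
#' @export
grid_spec <- function(crs, origin_x, origin_y, cell_size, n_rows, n_cols) {
  if (!is.character(crs) || length(crs) != 1L)
    stop("`crs` must be a single CRS identifier string", call. = FALSE)
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be positive", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  structure(
    list(crs = crs, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), cell_size = as.numeric(cell_size),
         n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s  %d x %d cells @ %g\n", x$crs,
              x$n_rows, x$n_cols, x$cell_size))
  e <- grid_extent(x)
  cat(sprintf("  extent: x [%g, %g)  y [%g, %g)\n",
              e["xmin"], e["xmax"], e["ymin"], e["ymax"]))
  invisible(x)
}

#' Extent of a grid
#'
#' @param grid A [grid_spec()].
#' @return Named numeric vector `xmin, xmax, ymin, ymax` (half-open).
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin_x,
    xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymin = grid$origin_y - grid$n_rows * grid$cell_size,
    ymax = grid$origin_y)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with `x` (length `n_cols`, west to east) and `y`
#'   (length `n_rows`, north to south).
#' @export
grid_centers <- function(grid) {
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

grids_identical <- function(a, b, tol = 1e-9) {
  a$crs == b$crs && a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Geographical processing levels
#'
#' Three nested processing levels are defined: `LOCAL` (highest resolution,
#' metric UTM zone 32N grid over north-eastern Italy), `COUNTRY` (Italy,
#' same metric CRS, coarser), and `CONTINENTAL` (western Europe, geographic
#' WGS84 CRS, coarsest; it does not share a lattice with the metric levels).
#' The metric levels share one master kilometer lattice anchored at a fixed
#' round-kilometer corner so that rasters of different resolutions have
#' coincident cell boundaries.
#'
#' @param code One of `"LOCAL"`, `"COUNTRY"`, `"CONTINENTAL"`.
#' @return A list with `code`, `crs` and `extent` (named vector as in
#'   [grid_extent()]).
#' @export
level_info <- function(code = c("LOCAL", "COUNTRY", "CONTINENTAL")) {
  code <- match.arg(code)
  switch(code,
    LOCAL = list(code = "LOCAL", crs = "EPSG:32632",
                 extent = c(xmin = 600000, xmax = 900000,
                            ymin = 4980000, ymax = 5230000)),
    COUNTRY = list(code = "COUNTRY", crs = "EPSG:32632",
                   extent = c(xmin = 290000, xmax = 1330000,
                              ymin = 3930000, ymax = 5230000)),
    CONTINENTAL = list(code = "CONTINENTAL", crs = "EPSG:4326",
                       extent = c(xmin = -11, xmax = 25,
                                  ymin = 34, ymax = 61)))
}

#' Master grid for a level
#'
#' The metric master lattice is anchored at the round-kilometer top-left
#' corner of the level extent; any cell size that is an integer multiple or
#' submultiple of 1000 m produces cell boundaries coincident with it.
#'
#' @param level Level code.
#' @param cell_size Cell size in CRS units (meters for metric levels,
#'   degrees for `CONTINENTAL`).
#' @return A [grid_spec()] covering the level extent at `cell_size`.
#' @export
master_grid <- function(level = c("LOCAL", "COUNTRY", "CONTINENTAL"),
                        cell_size = 1000) {
  info <- level_info(match.arg(level))
  e <- info$extent
  n_cols <- ceiling((e["xmax"] - e["xmin"]) / cell_size - 1e-9)
  n_rows <- ceiling((e["ymax"] - e["ymin"]) / cell_size - 1e-9)
  grid_spec(info$crs, e[["xmin"]], e[["ymax"]], cell_size, n_rows, n_cols)
}

#' Raster layer bound to a grid
#'
#' The basic gridded-value container: a numeric matrix (`n_rows x n_cols`,
#' row 1 = northernmost) bound to a [grid_spec()], with `NA` marking nodata
#' cells, plus the variable code, processing level and timestamp needed to
#' catalog the layer.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix matching the grid dimensions, or a single
#'   number recycled to a constant field. `NA` is nodata.
#' @param variable Variable code (e.g. `"LST"`, `"NDVI"`, `"PREC"`, `"DEM"`).
#' @param level Level code or `NA`.
#' @param timestamp A `Date` (or `NA`) the layer refers to.
#' @param overpass Optional overpass tag for sub-daily products, e.g.
#'   `"TERRA-DAY"`.
#' @return An object of class `raster_layer`.
#' @examples
#' g <- grid_spec("EPSG:32632", 0, 1000, 100, 4, 4)
#' r <- raster_layer(g, matrix(runif(16), 4, 4), variable = "NDVI")
#' @export
raster_layer <- function(grid, values, variable = NA_character_,
                         level = NA_character_, timestamp = as.Date(NA),
                         overpass = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("values are %d x %d but grid is %d x %d",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols),
         call. = FALSE)
  if (any(is.infinite(values)))
    stop("values must be finite or NA", call. = FALSE)
  structure(
    list(grid = grid, values = values, variable = variable, level = level,
         timestamp = as.Date(timestamp), overpass = overpass),
    class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values
  nval <- sum(!is.na(v))
  cat(sprintf("<raster_layer> %s %s %s%s\n",
              ifelse(is.na(x$variable), "?", x$variable),
              ifelse(is.na(x$level), "", x$level),
              ifelse(is.na(x$timestamp), "", format(x$timestamp)),
              if (!is.null(x$overpass)) paste0(" ", x$overpass) else ""))
  cat(sprintf("  %d x %d @ %g (%s); %d valid, %d nodata\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size, x$grid$crs,
              nval, length(v) - nval))
  if (nval > 0)
    cat(sprintf("  range: [%g, %g]\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

#' Count of nodata cells in a layer
#' @param layer A [raster_layer()].
#' @return Integer count of `NA` cells.
#' @export
nodata_count <- function(layer) sum(is.na(layer$values))

#' Crop a layer to a bounding box
#'
#' Keeps the cells whose centers fall inside the half-open box. Used both as
#' a user operation and in commutation tests (index-then-crop equals
#' crop-then-index).
#'
#' @param layer A [raster_layer()].
#' @param extent Named vector `xmin, xmax, ymin, ymax` in the layer CRS.
#' @return A cropped [raster_layer()].
#' @export
crop_layer <- function(layer, extent) {
  ctr <- grid_centers(layer$grid)
  keep_c <- which(ctr$x >= extent[["xmin"]] & ctr$x < extent[["xmax"]])
  keep_r <- which(ctr$y >= extent[["ymin"]] & ctr$y < extent[["ymax"]])
  if (!length(keep_r) || !length(keep_c))
    stop("crop extent does not intersect the layer", call. = FALSE)
  g <- layer$grid
  ng <- grid_spec(g$crs,
                  g$origin_x + (min(keep_c) - 1L) * g$cell_size,
                  g$origin_y - (min(keep_r) - 1L) * g$cell_size,
                  g$cell_size, length(keep_r), length(keep_c))
  raster_layer(ng, layer$values[keep_r, keep_c, drop = FALSE],
               layer$variable, layer$level, layer$timestamp, layer$overpass)
}
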