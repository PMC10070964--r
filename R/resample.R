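# Resampling, master-grid alignment and reprojection.

# Sample a layer at arbitrary points (same CRS), nearest-neighbour.
sample_nearest <- function(layer, px, py) {
  g <- layer$grid
  col <- floor((px - g$origin_x) / g$cell_size) + 1L
  row <- floor((g$origin_y - py) / g$cell_size) + 1L
  ok <- row >= 1L & row <= g$n_rows & col >= 1L & col <= g$n_cols
  out <- rep(NA_real_, length(px))
  if (any(ok))
    out[ok] <- layer$values[cbind(row[ok], col[ok])]
  out
}

# Bilinear sampling with edge extension; weights of nodata neighbours are
# dropped and the rest renormalized, so an isolated nodata cell does not
# poison its whole neighbourhood. All-nodata neighbourhood -> NA.
sample_bilinear <- function(layer, px, py) {
  g <- layer$grid
  v <- layer$values
  gx <- (px - g$origin_x) / g$cell_size + 0.5
  gy <- (g$origin_y - py) / g$cell_size + 0.5
  inside <- gx >= 0.5 - 1e-9 & gx <= g$n_cols + 0.5 + 1e-9 &
            gy >= 0.5 - 1e-9 & gy <= g$n_rows + 0.5 + 1e-9
  j0 <- pmin(pmax(floor(gx), 1L), g$n_cols); j1 <- pmin(j0 + 1L, g$n_cols)
  i0 <- pmin(pmax(floor(gy), 1L), g$n_rows); i1 <- pmin(i0 + 1L, g$n_rows)
  wx <- pmin(pmax(gx - floor(gx), 0), 1); wx[floor(gx) < 1] <- 0
  wy <- pmin(pmax(gy - floor(gy), 0), 1); wy[floor(gy) < 1] <- 0
  vals <- cbind(v[cbind(i0, j0)], v[cbind(i0, j1)],
                v[cbind(i1, j0)], v[cbind(i1, j1)])
  w <- cbind((1 - wx) * (1 - wy), wx * (1 - wy),
             (1 - wx) * wy, wx * wy)
  w[is.na(vals)] <- 0
  tot <- rowSums(w)
  vals[is.na(vals)] <- 0
  out <- ifelse(tot > 0, rowSums(vals * w) / tot, NA_real_)
  out[!inside] <- NA_real_
  out
}

#' Resample a layer onto a target grid
#'
#' Engine behind [align_to_master()] and [reproject()]. `nearest` and
#' `bilinear` sample the source at each target cell center; `block-mean`
#' averages the valid source cells whose centers fall inside each target
#' cell (the right choice when coarsening). Nodata propagates: a block with
#' no valid source cell, or a point outside the source extent, is nodata.
#'
#' @param layer Source [raster_layer()].
#' @param target_grid Target [grid_spec()] in the same CRS.
#' @param method One of `"nearest"`, `"bilinear"`, `"block-mean"`.
#' @return A [raster_layer()] on `target_grid`.
#' @export
resample_to_grid <- function(layer,
                             target_grid,
                             method = c("bilinear", "nearest", "block-mean")) {
  method <- match.arg(method)
  if (layer$grid$crs != target_grid$crs)
    stop("source and target CRS differ; use reproject()", call. = FALSE)
  if (grids_identical(layer$grid, target_grid)) return(layer)
  tg <- target_grid
  if (method == "block-mean") {
    sc <- grid_centers(layer$grid)
    cx <- rep(sc$x, each = layer$grid$n_rows)
    cy <- rep(sc$y, times = layer$grid$n_cols)
    tc <- floor((cx - tg$origin_x) / tg$cell_size) + 1L
    tr <- floor((tg$origin_y - cy) / tg$cell_size) + 1L
    v <- as.vector(layer$values)
    keep <- !is.na(v) & tr >= 1L & tr <= tg$n_rows & tc >= 1L & tc <= tg$n_cols
    out <- matrix(NA_real_, tg$n_rows, tg$n_cols)
    if (any(keep)) {
      lin <- tr[keep] + (tc[keep] - 1L) * tg$n_rows
      agg <- rowsum(cbind(v[keep], 1), lin)
      out[as.integer(rownames(agg))] <- agg[, 1] / agg[, 2]
    }
  } else {
    ctr <- grid_centers(tg)
    px <- rep(ctr$x, each = tg$n_rows)
    py <- rep(ctr$y, times = tg$n_cols)
    smp <- if (method == "nearest") sample_nearest(layer, px, py)
           else sample_bilinear(layer, px, py)
    out <- matrix(smp, tg$n_rows, tg$n_cols)
  }
  raster_layer(tg, out, layer$variable, layer$level, layer$timestamp,
               layer$overpass)
}

#' Align a layer to the master grid
#'
#' Builds the smallest grid at the master cell size whose cell boundaries
#' coincide with the master lattice and which covers the layer, then
#' resamples onto it. A layer already on the master lattice is returned
#' unchanged, so alignment is idempotent. If the layer is in a different CRS
#' the supported transform is applied (via [reproject()]).
#'
#' @param layer A [raster_layer()].
#' @param master A [grid_spec()] defining the lattice (see [master_grid()]).
#' @param method Resampling method, see [resample_to_grid()].
#' @return A [raster_layer()] whose origin differs from the master origin by
#'   integer multiples of the master cell size.
#' @export
align_to_master <- function(layer, master,
                            method = c("bilinear", "nearest", "block-mean")) {
  method <- match.arg(method)
  cs <- master$cell_size
  if (layer$grid$crs != master$crs) {
    e <- grid_extent(layer$grid)
    crn <- transform_points(c(e["xmin"], e["xmax"], e["xmin"], e["xmax"]),
                            c(e["ymin"], e["ymin"], e["ymax"], e["ymax"]),
                            layer$grid$crs, master$crs)
    e <- c(xmin = min(crn[, 1]), xmax = max(crn[, 1]),
           ymin = min(crn[, 2]), ymax = max(crn[, 2]))
  } else e <- grid_extent(layer$grid)
  x0 <- master$origin_x + floor((e[["xmin"]] - master$origin_x) / cs + 1e-9) * cs
  y0 <- master$origin_y - floor((master$origin_y - e[["ymax"]]) / cs + 1e-9) * cs
  n_cols <- max(1, ceiling((e[["xmax"]] - x0) / cs - 1e-9))
  n_rows <- max(1, ceiling((y0 - e[["ymin"]]) / cs - 1e-9))
  tg <- grid_spec(master$crs, x0, y0, cs, n_rows, n_cols)
  if (layer$grid$crs != master$crs)
    reproject(layer, master$crs, tg,
              method = if (method == "nearest") "nearest" else "bilinear")
  else
    resample_to_grid(layer, tg, method)
}

#' Aggregate a layer by an integer factor
#'
#' Each output cell is the mean of the valid input cells in its
#' `factor x factor` block; a block with no valid cell is nodata. Dimensions
#' not divisible by `factor` are padded with nodata on the south/east edges.
#'
#' @param layer A [raster_layer()].
#' @param factor Positive integer aggregation factor (e.g. 20 takes 10 m
#'   bands to the 200 m product resolution).
#' @return A [raster_layer()] with `cell_size * factor`.
#' @export
block_aggregate <- function(layer, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(layer)
  g <- layer$grid
  nr <- ceiling(g$n_rows / factor) * factor
  nc <- ceiling(g$n_cols / factor) * factor
  v <- matrix(NA_real_, nr, nc)
  v[seq_len(g$n_rows), seq_len(g$n_cols)] <- layer$values
  nro <- nr %/% factor; nco <- nc %/% factor
  # fold each factor x factor block into one slice of a 4-d array
  dim(v) <- c(factor, nro, factor, nco)
  sums <- apply(v, c(2, 4), function(b) sum(b, na.rm = TRUE))
  cnts <- apply(v, c(2, 4), function(b) sum(!is.na(b)))
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  ng <- grid_spec(g$crs, g$origin_x, g$origin_y, g$cell_size * factor,
                  nro, nco)
  raster_layer(ng, out, layer$variable, layer$level, layer$timestamp,
               layer$overpass)
}

# Nearest-neighbour disaggregation: replicate each cell factor x factor.
disaggregate_nearest <- function(layer, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(layer)
  g <- layer$grid
  idx_r <- rep(seq_len(g$n_rows), each = factor)
  idx_c <- rep(seq_len(g$n_cols), each = factor)
  ng <- grid_spec(g$crs, g$origin_x, g$origin_y, g$cell_size / factor,
                  g$n_rows * factor, g$n_cols * factor)
  raster_layer(ng, layer$values[idx_r, idx_c, drop = FALSE],
               layer$variable, layer$level, layer$timestamp, layer$overpass)
}

#' Reproject a layer onto a grid in another CRS
#'
#' Samples the source layer at each target cell center after transforming
#' the center coordinates into the source CRS. Continuous fields use
#' bilinear sampling; categorical fields (e.g. land-cover classes) must use
#' nearest-neighbour.
#'
#' @param layer Source [raster_layer()].
#' @param target_crs Target CRS identifier.
#' @param target_grid Target [grid_spec()] in `target_crs`.
#' @param method `"bilinear"` (continuous, default) or `"nearest"`
#'   (categorical).
#' @return A [raster_layer()] on `target_grid`.
#' @export
reproject <- function(layer, target_crs, target_grid,
                      method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (target_grid$crs != target_crs)
    stop("`target_grid` CRS does not match `target_crs`", call. = FALSE)
  if (layer$grid$crs == target_crs)
    return(resample_to_grid(layer, target_grid, method))
  ctr <- grid_centers(target_grid)
  px <- rep(ctr$x, each = target_grid$n_rows)
  py <- rep(ctr$y, times = target_grid$n_cols)
  src <- transform_points(px, py, target_crs, layer$grid$crs)
  smp <- if (method == "nearest") sample_nearest(layer, src[, 1], src[, 2])
         else sample_bilinear(layer, src[, 1], src[, 2])
  raster_layer(target_grid, matrix(smp, target_grid$n_rows, target_grid$n_cols),
               layer$variable, layer$level, layer$timestamp, layer$overpass)
}
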