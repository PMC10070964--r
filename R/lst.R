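# Land-surface-temperature cleaning, lapse-rate modelling, reconstruction
# and compositing.

#' Scale raw LST digital numbers to degrees Celsius
#'
#' Thermal products ship LST as scaled Kelvin digital numbers; the standard
#' convention is 0.02 K per digital number with 0 as the fill value. Output
#' is in degrees Celsius.
#'
#' @param dn_layer [raster_layer()] of non-negative digital numbers.
#' @param scale Kelvin per digital number.
#' @param offset Additive offset applied after scaling (Kelvin-to-Celsius).
#' @return [raster_layer()] in degrees Celsius; fill values become nodata.
#' @examples
#' g <- grid_spec("EPSG:32632", 0, 200, 100, 1, 2)
#' scale_lst(raster_layer(g, matrix(c(14825, 0), 1, 2)))$values
#' @export
scale_lst <- function(dn_layer, scale = 0.02, offset = -273.15) {
  v <- dn_layer$values
  if (any(v < 0, na.rm = TRUE))
    stop("digital numbers must be non-negative", call. = FALSE)
  out <- v * scale + offset
  out[!is.na(v) & v == 0] <- NA_real_
  raster_layer(dn_layer$grid, out, "LST", dn_layer$level,
               dn_layer$timestamp, dn_layer$overpass)
}

#' Remove distribution outliers from a layer
#'
#' Robust per-scene screen: cells farther than `k_mad` median absolute
#' deviations (scaled, consistent with a normal SD) from the scene median
#' become nodata. The MAD is floored at a small epsilon so constant fields
#' pass through unchanged.
#'
#' @param layer A [raster_layer()].
#' @param k_mad Rejection threshold in MAD units (default 5).
#' @param min_valid Minimum valid cells needed to attempt filtering; below
#'   this the layer is returned unchanged with a warning.
#' @return The filtered [raster_layer()].
#' @export
filter_distribution <- function(layer, k_mad = 5, min_valid = 25L) {
  if (k_mad <= 0) stop("`k_mad` must be positive", call. = FALSE)
  v <- layer$values
  ok <- !is.na(v)
  if (sum(ok) < min_valid) {
    warning("too few valid cells for distribution filtering; layer unchanged")
    return(layer)
  }
  med <- stats::median(v[ok])
  mad <- max(stats::mad(v[ok]), 1e-6)
  v[ok & abs(v - med) > k_mad * mad] <- NA_real_
  raster_layer(layer$grid, v, layer$variable, layer$level, layer$timestamp,
               layer$overpass)
}

#' Fit the elevation lapse-rate model of a temperature scene
#'
#' Ordinary least squares of scene temperature on elevation over the jointly
#' valid cells. The fitted slope is the scene's apparent lapse rate
#' (typically near -0.0065 degC/m, the environmental lapse rate); the model
#' anchors both outlier screening ([filter_lapse_outliers()]) and gap
#' reconstruction ([reconstruct_gaps()]).
#'
#' @param layer Temperature [raster_layer()] in degrees Celsius.
#' @param dem Elevation [raster_layer()] on the same grid, meters.
#' @param min_valid Minimum jointly valid cells required.
#' @return An object of class `lapse_model` with components `intercept`
#'   (degC at elevation 0), `slope` (degC per meter), `residual_sd` (degC)
#'   and `n_fit`.
#' @examples
#' g <- grid_spec("EPSG:32632", 0, 4000, 200, 20, 20)
#' dem <- raster_layer(g, matrix(runif(400, 0, 2000), 20, 20), "DEM")
#' lst <- raster_layer(g, 28 - 0.0065 * dem$values, "LST")
#' fit_lapse_model(lst, dem)
#' @export
fit_lapse_model <- function(layer, dem, min_valid = 30L) {
  if (!grids_identical(layer$grid, dem$grid))
    stop("temperature and DEM are on different grids", call. = FALSE)
  ok <- !is.na(layer$values) & !is.na(dem$values)
  n <- sum(ok)
  if (n < min_valid)
    stop(sprintf("only %d jointly valid cells (need %d)", n, min_valid),
         call. = FALSE)
  elev <- dem$values[ok]
  if (stats::var(elev) < 1e-12)
    stop("degenerate DEM: elevation has zero variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, elev), layer$values[ok])
  rsd <- if (n > 2) sqrt(sum(fit$residuals^2) / (n - 2)) else 0
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 residual_sd = rsd, n_fit = n),
            class = "lapse_model")
}

#' @export
print.lapse_model <- function(x, ...) {
  cat("<lapse_model> temperature ~ elevation (OLS)\n")
  cat(sprintf("  intercept: %.3f degC   slope: %.5g degC/m\n",
              x$intercept, x$slope))
  cat(sprintf("  residual SD: %.3f degC   n = %d cells\n",
              x$residual_sd, x$n_fit))
  invisible(x)
}

#' @export
coef.lapse_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict temperature from elevation with a lapse model
#'
#' @param object A `lapse_model`.
#' @param elevation Numeric vector or matrix of elevations in meters, or a
#'   DEM [raster_layer()].
#' @param ... Unused.
#' @return Predicted temperatures, same shape as `elevation` (a
#'   [raster_layer()] in, a [raster_layer()] out).
#' @export
predict.lapse_model <- function(object, elevation, ...) {
  if (inherits(elevation, "raster_layer"))
    return(raster_layer(elevation$grid,
                        object$intercept + object$slope * elevation$values,
                        "LST", elevation$level))
  object$intercept + object$slope * elevation
}

#' @export
summary.lapse_model <- function(object, ...) {
  cat(sprintf(
    "Lapse-rate fit on %d cells: %.2f %+.5g * elevation (degC), sigma = %.3f\n",
    object$n_fit, object$intercept, object$slope, object$residual_sd))
  invisible(object)
}

#' Remove cells inconsistent with the elevation lapse model
#'
#' Cells whose residual from the fitted lapse line exceeds
#' `k_sigma * residual_sd` become nodata. With a zero residual SD only
#' exact-match cells survive.
#'
#' @param layer Temperature [raster_layer()].
#' @param dem Elevation [raster_layer()] on the same grid.
#' @param model A [fit_lapse_model()] result.
#' @param k_sigma Rejection threshold in residual SD units (default 3).
#' @return The filtered [raster_layer()].
#' @export
filter_lapse_outliers <- function(layer, dem, model, k_sigma = 3) {
  if (!grids_identical(layer$grid, dem$grid))
    stop("temperature and DEM are on different grids", call. = FALSE)
  if (k_sigma <= 0) stop("`k_sigma` must be positive", call. = FALSE)
  pred <- model$intercept + model$slope * dem$values
  v <- layer$values
  bad <- !is.na(v) & !is.na(pred) &
    abs(v - pred) > k_sigma * model$residual_sd
  v[bad] <- NA_real_
  raster_layer(layer$grid, v, layer$variable, layer$level, layer$timestamp,
               layer$overpass)
}

#' Reconstruct temperature gaps from elevation
#'
#' Fills every nodata cell with the lapse-model prediction at the cell's
#' elevation plus a smooth residual surface interpolated (thin-plate
#' spline, exact at anchors by default) from the surrounding valid cells.
#' Valid cells keep their observed values, so the output is gap-free and
#' agrees with the input wherever the input was observed. When the
#' observations are coarser than the DEM they are first assigned to the
#' fine grid by nearest neighbour, yielding the higher-resolution product.
#'
#' @param layer Temperature [raster_layer()], possibly with gaps, on the
#'   DEM grid or an integer multiple of its cell size.
#' @param dem Elevation [raster_layer()] on the target (finer) grid.
#' @param model A [fit_lapse_model()] result for this scene.
#' @param max_anchors Residual anchors are spatially subsampled down to at
#'   most this many cells to bound the dense spline solve.
#' @param smoothing Spline smoothing; 0 keeps the surface exact at anchors.
#' @return A gap-free [raster_layer()] on the DEM grid.
#' @export
reconstruct_gaps <- function(layer, dem, model, max_anchors = 400L,
                             smoothing = 0) {
  if (!grids_identical(layer$grid, dem$grid)) {
    ratio <- layer$grid$cell_size / dem$grid$cell_size
    if (abs(ratio - round(ratio)) > 1e-6 || ratio < 1)
      stop("observation grid is not an integer multiple of the DEM grid",
           call. = FALSE)
    layer <- disaggregate_nearest(layer, as.integer(round(ratio)))
    if (!grids_identical(layer$grid, dem$grid))
      stop("observation grid cannot be matched to the DEM grid",
           call. = FALSE)
  }
  v <- layer$values
  ok <- !is.na(v) & !is.na(dem$values)
  if (!any(ok))
    stop("no valid cells in the scene; cannot anchor residuals",
         call. = FALSE)
  if (!anyNA(v)) return(layer)
  pred <- model$intercept + model$slope * dem$values
  resid <- v - pred
  ctr <- grid_centers(layer$grid)
  xx <- rep(ctr$x, each = layer$grid$n_rows)
  yy <- rep(ctr$y, times = layer$grid$n_cols)
  anchors <- which(ok)
  if (length(anchors) > max_anchors)
    anchors <- anchors[round(seq(1, length(anchors),
                                 length.out = max_anchors))]
  rng <- range(resid[anchors])
  gap <- which(is.na(v))
  if (diff(rng) < 1e-12) {
    rfill <- rep(resid[anchors][1], length(gap))
  } else {
    fit <- tps_fit(xx[anchors], yy[anchors], resid[anchors],
                   smoothing = smoothing)
    rfill <- tps_predict(fit, xx[gap], yy[gap])
  }
  v[gap] <- pred[gap] + rfill
  raster_layer(layer$grid, v, layer$variable, layer$level, layer$timestamp,
               layer$overpass)
}

# Start days of the 8-day compositing windows of a year (restart each year).
window_starts_8day <- function() seq(1L, 361L, by = 8L)

#' Composite acquisitions over an 8-day window
#'
#' Per-cell mean of the valid observations among the acquisitions falling in
#' the window starting at day-of-year `window_start_doy` (windows start at
#' day 1, 9, 17, ...; the last window of a year is short). Cells with no
#' valid observation stay nodata. The result is independent of acquisition
#' order.
#'
#' @param acquisitions List of [raster_layer()]s with timestamps, on one
#'   grid.
#' @param window_start_doy Window start day-of-year (1, 9, ..., 361).
#' @param year Calendar year of the window; defaults to the year of the
#'   first acquisition.
#' @return The composited [raster_layer()] timestamped at the window start.
#' @export
composite_8day <- function(acquisitions, window_start_doy, year = NULL) {
  if (!length(acquisitions)) stop("empty acquisition list", call. = FALSE)
  if (!(window_start_doy %in% window_starts_8day()))
    stop("`window_start_doy` must be one of 1, 9, 17, ..., 361",
         call. = FALSE)
  if (is.null(year))
    year <- as.integer(format(acquisitions[[1]]$timestamp, "%Y"))
  start <- as.Date(sprintf("%d-01-01", year)) + (window_start_doy - 1L)
  end <- min(start + 7L, as.Date(sprintf("%d-12-31", year)))
  grid <- acquisitions[[1]]$grid
  inwin <- Filter(function(a) {
    if (!grids_identical(a$grid, grid))
      stop("acquisitions are on different grids", call. = FALSE)
    !is.na(a$timestamp) && a$timestamp >= start && a$timestamp <= end
  }, acquisitions)
  if (!length(inwin))
    stop(sprintf("no acquisitions in window %s .. %s", start, end),
         call. = FALSE)
  # canonical accumulation order makes the result exactly independent of
  # the order acquisitions were supplied in
  ord <- order(vapply(inwin, function(a)
    paste(a$timestamp, a$overpass %||% ""), character(1)))
  inwin <- inwin[ord]
  sums <- matrix(0, grid$n_rows, grid$n_cols)
  cnts <- matrix(0L, grid$n_rows, grid$n_cols)
  for (a in inwin) {
    ok <- !is.na(a$values)
    sums[ok] <- sums[ok] + a$values[ok]
    cnts <- cnts + ok
  }
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  raster_layer(grid, out, acquisitions[[1]]$variable,
               acquisitions[[1]]$level, start)
}

#' Run the local LST chain for one day
#'
#' Chains the full local-level treatment for the (up to) four daily
#' acquisitions of one date: QC masking, distribution screening, lapse-model
#' fitting, lapse-based outlier removal, and DEM-based gap reconstruction
#' onto the fine grid. Emits one gap-free layer per acquisition.
#'
#' @param acquisitions List of [raster_layer()]s in degrees Celsius (one per
#'   satellite x overpass), with matching `qc` layers.
#' @param qc List of QC [raster_layer()]s, same order, or `NULL` to skip
#'   QC masking.
#' @param dem Elevation [raster_layer()] on the target fine grid.
#' @param policy A [qc_policy()].
#' @param k_mad,k_sigma Filter thresholds, see [filter_distribution()] and
#'   [filter_lapse_outliers()].
#' @param max_anchors Passed to [reconstruct_gaps()].
#' @return List of gap-free [raster_layer()]s on the DEM grid, one per
#'   acquisition, with `lapse_model` fits attached as attribute `"models"`.
#' @export
process_lst_day <- function(acquisitions, qc = NULL, dem,
                            policy = qc_policy(), k_mad = 5, k_sigma = 3,
                            max_anchors = 400L) {
  out <- vector("list", length(acquisitions))
  models <- vector("list", length(acquisitions))
  coarse_dem <- NULL
  for (i in seq_along(acquisitions)) {
    lyr <- acquisitions[[i]]
    if (!is.null(qc)) lyr <- apply_qc_mask(lyr, qc[[i]], policy)
    lyr <- filter_distribution(lyr, k_mad = k_mad)
    if (grids_identical(lyr$grid, dem$grid)) {
      dem_obs <- dem
    } else {
      if (is.null(coarse_dem))
        coarse_dem <- resample_to_grid(dem, lyr$grid, "block-mean")
      dem_obs <- coarse_dem
    }
    model <- fit_lapse_model(lyr, dem_obs)
    lyr <- filter_lapse_outliers(lyr, dem_obs, model, k_sigma = k_sigma)
    out[[i]] <- reconstruct_gaps(lyr, dem, model, max_anchors = max_anchors)
    models[[i]] <- model
  }
  tags <- vapply(acquisitions, function(a) a$overpass %||% NA_character_,
                 character(1))
  if (!anyNA(tags)) names(out) <- names(models) <- tags
  attr(out, "models") <- models
  out
}
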