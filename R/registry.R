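#' Product registry
#'
#' Registry of the gridded products the pipeline handles: for each
#' (variable, level) the source tag, the native resolution of the input
#' product, the target cell size the output is produced at, the temporal
#' cadence and the measurement units. Target cell sizes on the metric levels
#' are integer multiples or submultiples of 1000 m so every product snaps
#' to the shared kilometer master lattice. The two coarse precipitation
#' sources carry explicit targets (27 km for the 0.25-degree station-blend
#' reanalysis, 10 km for the 0.1-degree satellite product) because a naive
#' degree-to-kilometer conversion does not land on those values.
#'
#' @return A data frame with columns `variable`, `level`, `source`,
#'   `native_res`, `native_unit`, `target_cell_size`, `cadence`, `units`.
#' @export
product_registry <- function() {
  rbind(
    data.frame(variable = "LST",   level = "LOCAL",       source = "MODIS",
               native_res = 1000,  native_unit = "m",
               target_cell_size = 200,   cadence = "daily",  units = "degC"),
    data.frame(variable = "LST",   level = "COUNTRY",     source = "MODIS",
               native_res = 1000,  native_unit = "m",
               target_cell_size = 1000,  cadence = "8-day",  units = "degC"),
    data.frame(variable = "LST",   level = "CONTINENTAL", source = "MODIS",
               native_res = 1000,  native_unit = "m",
               target_cell_size = 1000,  cadence = "8-day",  units = "degC"),
    data.frame(variable = "NDVI",  level = "LOCAL",       source = "SENTINEL2",
               native_res = 10,    native_unit = "m",
               target_cell_size = 200,   cadence = "scene",  units = "index"),
    data.frame(variable = "NDVI",  level = "COUNTRY",     source = "MODIS",
               native_res = 1000,  native_unit = "m",
               target_cell_size = 1000,  cadence = "8-day",  units = "index"),
    data.frame(variable = "NDVI",  level = "CONTINENTAL", source = "MODIS",
               native_res = 1000,  native_unit = "m",
               target_cell_size = 1000,  cadence = "8-day",  units = "index"),
    data.frame(variable = "EVI",   level = "LOCAL",       source = "SENTINEL2",
               native_res = 10,    native_unit = "m",
               target_cell_size = 200,   cadence = "scene",  units = "index"),
    data.frame(variable = "EVI",   level = "COUNTRY",     source = "MODIS",
               native_res = 1000,  native_unit = "m",
               target_cell_size = 1000,  cadence = "8-day",  units = "index"),
    data.frame(variable = "EVI",   level = "CONTINENTAL", source = "MODIS",
               native_res = 1000,  native_unit = "m",
               target_cell_size = 1000,  cadence = "8-day",  units = "index"),
    data.frame(variable = "MNDWI", level = "LOCAL",       source = "SENTINEL2",
               native_res = 10,    native_unit = "m",
               target_cell_size = 200,   cadence = "scene",  units = "index"),
    data.frame(variable = "PREC",  level = "LOCAL",       source = "STATIONS",
               native_res = NA,    native_unit = "m",
               target_cell_size = 1000,  cadence = "daily",  units = "mm/day"),
    data.frame(variable = "PREC",  level = "COUNTRY",     source = "EOBS",
               native_res = 0.25,  native_unit = "deg",
               target_cell_size = 27000, cadence = "daily",  units = "mm/day"),
    data.frame(variable = "PREC",  level = "CONTINENTAL", source = "EOBS",
               native_res = 0.25,  native_unit = "deg",
               target_cell_size = 27000, cadence = "daily",  units = "mm/day"),
    data.frame(variable = "PREC",  level = "COUNTRY",     source = "GPM",
               native_res = 0.1,   native_unit = "deg",
               target_cell_size = 10000, cadence = "daily",  units = "mm/day"),
    data.frame(variable = "PREC",  level = "CONTINENTAL", source = "GPM",
               native_res = 0.1,   native_unit = "deg",
               target_cell_size = 10000, cadence = "daily",  units = "mm/day"),
    data.frame(variable = "DEM",   level = "LOCAL",       source = "SPOT",
               native_res = 25,    native_unit = "m",
               target_cell_size = 200,   cadence = "static", units = "m"),
    data.frame(variable = "LC",    level = "CONTINENTAL", source = "CORINE",
               native_res = 100,   native_unit = "m",
               target_cell_size = 100,   cadence = "static", units = "class"))
}

# Approximate ground length of one degree of latitude, used only for the
# fallback snap when no registry target exists for a source.
.km_per_degree <- 111.32

#' Snap a native resolution to the kilometer lattice
#'
#' Returns the target cell size in meters for a product: if the registry
#' declares an explicit target for the source, that constant wins; otherwise
#' the native resolution is converted to kilometers (degrees at
#' 111.32 km/deg) and rounded half-up to the nearest whole kilometer.
#'
#' @param native_res Native resolution of the input product (> 0).
#' @param unit Unit of `native_res`, `"m"` or `"deg"`.
#' @param source Optional source tag (e.g. `"EOBS"`, `"GPM"`); looked up in
#'   the registry. Unknown tags are an error.
#' @param registry A registry data frame, by default [product_registry()].
#' @return Target cell size in meters.
#' @examples
#' snap_resolution(0.25, unit = "deg", source = "EOBS")  # 27000
#' snap_resolution(0.1, unit = "deg", source = "GPM")    # 10000
#' snap_resolution(1000)                                 # 1000
#' @export
snap_resolution <- function(native_res, unit = c("m", "deg"), source = NULL,
                            registry = product_registry()) {
  unit <- match.arg(unit)
  if (!is.finite(native_res) || native_res <= 0)
    stop("`native_res` must be positive", call. = FALSE)
  if (!is.null(source)) {
    hit <- registry[registry$source == source, , drop = FALSE]
    if (nrow(hit) == 0L)
      stop(sprintf("unknown product source '%s' in registry", source),
           call. = FALSE)
    tgt <- unique(hit$target_cell_size)
    if (length(tgt) == 1L && is.finite(tgt)) return(tgt)
  }
  km <- if (unit == "deg") native_res * .km_per_degree else native_res / 1000
  max(1, floor(km + 0.5)) * 1000
}
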