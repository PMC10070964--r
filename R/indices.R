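#' Multispectral band set
#'
#' Bundles the surface-reflectance bands of one scene on a shared grid.
#' Reflectances are dimensionless, nominally in `[0, 1]`; integer-scaled
#' inputs (e.g. x 10000) should be divided by their declared scale on read.
#'
#' @param blue,green,red,nir,swir [raster_layer()]s of reflectance, or
#'   `NULL` for absent bands. All present bands must share one grid.
#' @param date Acquisition date.
#' @return An object of class `band_set`.
#' @export
band_set <- function(blue = NULL, green = NULL, red = NULL, nir = NULL,
                     swir = NULL, date = as.Date(NA)) {
  bands <- Filter(Negate(is.null),
                  list(blue = blue, green = green, red = red, nir = nir,
                       swir = swir))
  if (!length(bands)) stop("at least one band required", call. = FALSE)
  g <- bands[[1]]$grid
  for (b in bands) {
    if (!grids_identical(b$grid, g))
      stop("bands are on different grids", call. = FALSE)
    if (any(b$values < 0, na.rm = TRUE))
      stop("reflectance must be non-negative where valid", call. = FALSE)
  }
  structure(c(list(blue = blue, green = green, red = red, nir = nir,
                   swir = swir), list(grid = g, date = as.Date(date))),
            class = "band_set")
}

need_bands <- function(bands, which) {
  missing <- which[vapply(bands[which], is.null, logical(1))]
  if (length(missing))
    stop(sprintf("missing band(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
}

normalized_difference <- function(plus, minus, clip = TRUE) {
  den <- plus$values + minus$values
  out <- (plus$values - minus$values) / den
  out[!is.na(den) & den == 0] <- NA_real_
  if (clip) out <- pmin(pmax(out, -1), 1)
  out
}

#' Normalized Difference Vegetation Index
#'
#' `(NIR - Red) / (NIR + Red)`, clipped to `[-1, 1]`; zero denominators are
#' nodata. High values indicate photosynthetically active vegetation.
#'
#' @param bands A [band_set()] with `red` and `nir`.
#' @return An NDVI [raster_layer()].
#' @export
ndvi <- function(bands) {
  need_bands(bands, c("red", "nir"))
  raster_layer(bands$grid, normalized_difference(bands$nir, bands$red),
               "NDVI", timestamp = bands$date)
}

#' Enhanced Vegetation Index
#'
#' `G (NIR - Red) / (NIR + C1 Red - C2 Blue + L)` with the standard
#' coefficients G = 2.5, C1 = 6, C2 = 7.5, L = 1. The blue band and the
#' canopy-background term make it less prone to saturation than NDVI over
#' dense canopies; output is not clipped but near-zero denominators are
#' nodata.
#'
#' @param bands A [band_set()] with `red`, `nir`, `blue`.
#' @param g_coef,c1,c2,l_coef Formula coefficients.
#' @param eps Denominator magnitude below which the cell is nodata.
#' @return An EVI [raster_layer()].
#' @export
evi <- function(bands, g_coef = 2.5, c1 = 6, c2 = 7.5, l_coef = 1,
                eps = 1e-6) {
  need_bands(bands, c("red", "nir", "blue"))
  den <- bands$nir$values + c1 * bands$red$values -
    c2 * bands$blue$values + l_coef
  out <- g_coef * (bands$nir$values - bands$red$values) / den
  out[!is.na(den) & abs(den) < eps] <- NA_real_
  raster_layer(bands$grid, out, "EVI", timestamp = bands$date)
}

#' Modified Normalized Difference Water Index
#'
#' `(Green - SWIR) / (Green + SWIR)`, clipped to `[-1, 1]`; positive values
#' flag open water (candidate vector breeding sites).
#'
#' @param bands A [band_set()] with `green` and `swir`.
#' @return An MNDWI [raster_layer()].
#' @export
mndwi <- function(bands) {
  need_bands(bands, c("green", "swir"))
  raster_layer(bands$grid, normalized_difference(bands$green, bands$swir),
               "MNDWI", timestamp = bands$date)
}

#' Interleave a 16-day series with pairwise midpoints
#'
#' For every pair of consecutive layers `(t, t + 16 days)` a per-cell
#' nodata-aware mean timestamped `t + 8 days` is inserted between them,
#' aligning a 16-day vegetation-index series to the 8-day thermal cadence.
#' Originals are preserved; a cell valid in only one parent keeps that
#' parent's value.
#'
#' @param series List of [raster_layer()]s with strictly increasing
#'   timestamps at nominal 16-day spacing.
#' @return List of [raster_layer()]s at 8-day spacing (originals plus
#'   midpoints); fewer than two inputs are returned unchanged.
#' @export
pairwise_temporal_average <- function(series) {
  if (length(series) < 2L) return(series)
  ts <- as.Date(vapply(series, function(l) as.character(l$timestamp),
                       character(1)))
  if (any(diff(as.numeric(ts)) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  out <- list(series[[1]])
  for (i in seq_len(length(series) - 1L)) {
    a <- series[[i]]; b <- series[[i + 1L]]
    if (!grids_identical(a$grid, b$grid))
      stop("series layers are on different grids", call. = FALSE)
    va <- a$values; vb <- b$values
    s <- ifelse(is.na(va), 0, va) + ifelse(is.na(vb), 0, vb)
    n <- (!is.na(va)) + (!is.na(vb))
    mid <- ifelse(n > 0, s / n, NA_real_)
    out[[length(out) + 1L]] <-
      raster_layer(a$grid, mid, a$variable, a$level, ts[i] + 8L)
    out[[length(out) + 1L]] <- b
  }
  out
}
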