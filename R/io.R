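# Plain-text raster serialization: ESRI ASCII Grid (.asc) with a sidecar
# .prj file carrying the CRS code. The format is understood by GDAL, GRASS
# and ArcGIS; nodata is serialized as a declared sentinel value.

#' Write a raster layer as an ESRI ASCII grid
#'
#' Values are written at full precision (up to 15 significant digits), so
#' integer-valued data round-trip exactly. The CRS code is written to a
#' sidecar file with the same stem and extension `.prj`.
#'
#' @param layer A [raster_layer()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Sentinel value replacing `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  e <- grid_extent(g)
  v <- layer$values
  if (any(v == nodata, na.rm = TRUE))
    stop("a valid cell equals the nodata sentinel; choose another sentinel",
         call. = FALSE)
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", e[["xmin"]]),
    sprintf("yllcorner %.10g", e[["ymin"]]),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  writeLines(apply(v, 1L, function(r)
    paste(formatC(r, format = "g", digits = 15), collapse = " ")), con)
  writeLines(g$crs, sub("\\.[^.]*$", ".prj", path))
  invisible(path)
}

#' Read an ESRI ASCII grid as a raster layer
#'
#' Reads the `.asc` header and value block; the CRS is taken from the
#' sidecar `.prj` if present, otherwise from `crs`. If the filename follows
#' the catalog naming convention (see [parse_name()]) the variable, level,
#' date and overpass tags are recovered from it.
#'
#' @param path Path to the `.asc` file.
#' @param crs Fallback CRS identifier if no sidecar exists.
#' @return A [raster_layer()].
#' @export
read_ascii_grid <- function(path, crs = "EPSG:32632") {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "cellsize", "nodata_value"))) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]]))
      stop(sprintf("malformed ascii grid header: missing %s", k),
           call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = lines[(i + 1L):length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ascii grid value block does not match header dimensions",
         call. = FALSE)
  v <- matrix(vals, nr, nc, byrow = TRUE)
  v[v == nodata] <- NA_real_
  prj <- sub("\\.[^.]*$", ".prj", path)
  if (file.exists(prj)) crs <- trimws(readLines(prj, n = 1L))
  g <- grid_spec(crs, hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                 hdr$cellsize, nr, nc)
  meta <- tryCatch(parse_name(basename(path)), error = function(e) NULL)
  if (is.null(meta))
    raster_layer(g, v)
  else
    raster_layer(g, v, variable = meta$variable, level = meta$level,
                 timestamp = meta$date, overpass = meta$overpass)
}
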