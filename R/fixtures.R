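# Seeded synthetic fixtures with known ground truth: DEM, thermal scenes
# with cloud gaps, multispectral patch scenes, and station networks in
# multiple provider dialects. Everything is a deterministic function of the
# configured seed; the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fixture configuration
#'
#' Fixes the study conditions every synthetic fixture is generated under:
#' grid geometry (a small window of the local 200 m master lattice),
#' terrain relief, the environmental lapse rate (-0.0065 degC/m), scene
#' noise, cloud-gap fraction and station count. A fixed seed gives
#' bit-identical fixtures.
#'
#' @param seed Integer RNG seed.
#' @param n_rows,n_cols Fixture grid dimensions (cells).
#' @param cell_size Cell size in meters (local fine resolution, 200 m).
#' @param dem_relief Maximum elevation above the valley floor, meters.
#' @param lapse_rate Temperature lapse with elevation, degC per meter.
#' @param t0 Sea-level daytime temperature, degC.
#' @param noise_sd Observation noise SD, degC.
#' @param cloud_fraction Fraction of cells cloud-contaminated in thermal
#'   scenes, `[0, 1]`.
#' @param n_stations Stations in the synthetic network.
#' @param reflectance_noise Reflectance noise SD in multispectral scenes.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_rows = 60L, n_cols = 60L,
                           cell_size = 200, dem_relief = 2000,
                           lapse_rate = -0.0065, t0 = 30, noise_sd = 1,
                           cloud_fraction = 0.3, n_stations = 25L,
                           reflectance_noise = 0.01) {
  stopifnot(cloud_fraction >= 0, cloud_fraction <= 1, noise_sd >= 0,
            dem_relief >= 0, n_stations >= 1)
  info <- level_info("LOCAL")
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), cell_size = cell_size,
                 origin_x = info$extent[["xmin"]],
                 origin_y = info$extent[["ymax"]],
                 dem_relief = dem_relief, lapse_rate = lapse_rate, t0 = t0,
                 noise_sd = noise_sd, cloud_fraction = cloud_fraction,
                 n_stations = as.integer(n_stations),
                 reflectance_noise = reflectance_noise),
            class = "fixture_config")
}

fixture_grid <- function(config, cell_size = config$cell_size,
                         factor = 1L) {
  grid_spec("EPSG:32632", config$origin_x, config$origin_y,
            cell_size, config$n_rows * factor, config$n_cols * factor)
}

# Smooth positive field: sum of Gaussian hills, rescaled to [0, amplitude].
gaussian_hills <- function(grid, n_hills, amplitude) {
  ctr <- grid_centers(grid)
  e <- grid_extent(grid)
  f <- matrix(0, grid$n_rows, grid$n_cols)
  if (amplitude <= 0) return(f)
  for (h in seq_len(n_hills)) {
    cx <- stats::runif(1, e[["xmin"]], e[["xmax"]])
    cy <- stats::runif(1, e[["ymin"]], e[["ymax"]])
    sx <- stats::runif(1, 0.1, 0.35) * (e[["xmax"]] - e[["xmin"]])
    sy <- stats::runif(1, 0.1, 0.35) * (e[["ymax"]] - e[["ymin"]])
    amp <- stats::runif(1, 0.3, 1)
    f <- f + amp * outer(exp(-(ctr$y - cy)^2 / (2 * sy^2)),
                         exp(-(ctr$x - cx)^2 / (2 * sx^2)))
  }
  rng <- range(f)
  if (diff(rng) > 0) f <- (f - rng[1]) / diff(rng) * amplitude
  f
}

#' Synthetic digital elevation model
#'
#' Smooth positive elevation surface (sum of Gaussian hills) on the fine
#' fixture grid, scaled to `[0, dem_relief]`.
#'
#' @param config A [fixture_config()].
#' @return A `DEM` [raster_layer()].
#' @export
make_dem <- function(config) {
  with_seed(config$seed, {
    g <- fixture_grid(config)
    raster_layer(g, gaussian_hills(g, 6L, config$dem_relief), "DEM",
                 "LOCAL")
  })
}

# The four daily thermal overpasses and their diurnal temperature offsets.
.overpasses <- c("TERRA-DAY" = 0, "AQUA-DAY" = 2,
                 "TERRA-NIGHT" = -10, "AQUA-NIGHT" = -8)

#' Synthetic thermal day: truth, observations and quality band
#'
#' Emits the four daily acquisitions (two satellites x day/night) of one
#' date. Truth is `t0 + overpass offset + lapse_rate * elevation` plus a
#' smooth anomaly; observations add Gaussian noise, and a random
#' `cloud_fraction` of cells is cloud-contaminated (strong cold bias) and
#' flagged "not produced" (mandatory-QA 3) in the QC band, with clear cells
#' flagged good (0).
#'
#' @param config A [fixture_config()].
#' @param dem DEM from [make_dem()] (regenerated if `NULL`).
#' @param date Acquisition date.
#' @return List with `truth`, `observed`, `qc` (each a list of four
#'   [raster_layer()]s keyed by overpass tag) and `dem`.
#' @export
make_lst_scene <- function(config, dem = NULL,
                           date = as.Date("2020-07-01")) {
  if (is.null(dem)) dem <- make_dem(config)
  g <- dem$grid
  with_seed(config$seed + 1L, {
    anomaly <- gaussian_hills(g, 3L, 2) - 1
    truth <- observed <- qc <- list()
    for (op in names(.overpasses)) {
      tr <- config$t0 + .overpasses[[op]] +
        config$lapse_rate * dem$values + anomaly
      noise <- matrix(stats::rnorm(length(tr), 0, config$noise_sd),
                      nrow(tr), ncol(tr))
      cloud <- matrix(stats::runif(length(tr)) < config$cloud_fraction,
                      nrow(tr), ncol(tr))
      obs <- tr + noise
      obs[cloud] <- obs[cloud] - 25
      truth[[op]] <- raster_layer(g, tr, "LST", "LOCAL", date, op)
      observed[[op]] <- raster_layer(g, obs, "LST", "LOCAL", date, op)
      qc[[op]] <- raster_layer(g, ifelse(cloud, 3, 0), "QC", "LOCAL",
                               date, op)
    }
    list(truth = truth, observed = observed, qc = qc, dem = dem)
  })
}

#' Synthetic multispectral scene with known patches
#'
#' Paints three patches (vegetation / bare soil / water) on a 10 m grid
#' with band signatures chosen so NDVI, EVI and MNDWI have known signs and
#' magnitudes inside each patch, plus an optional cloud block in the
#' scene-classification band (class 9).
#'
#' @param config A [fixture_config()].
#' @param cell_size Band cell size in meters (native 10 m).
#' @param date Acquisition date.
#' @return List with `bands` (a [band_set()]), `scl` (class
#'   [raster_layer()]) and `truth_masks` (logical matrices `vegetation`,
#'   `bare`, `water`, `cloud`).
#' @export
make_multispectral_scene <- function(config, cell_size = 10,
                                     date = as.Date("2020-07-01")) {
  factor <- as.integer(round(config$cell_size / cell_size))
  g <- fixture_grid(config, cell_size, factor)
  nr <- g$n_rows; nc <- g$n_cols
  third <- nc %/% 3L
  veg <- bare <- water <- matrix(FALSE, nr, nc)
  veg[, seq_len(third)] <- TRUE
  bare[, (third + 1L):(2L * third)] <- TRUE
  water[, (2L * third + 1L):nc] <- TRUE
  sig <- list(  #  blue green  red  nir swir  scl
    veg   = c(0.04, 0.08, 0.06, 0.50, 0.25, 4),
    bare  = c(0.12, 0.18, 0.25, 0.30, 0.35, 5),
    water = c(0.06, 0.12, 0.04, 0.02, 0.01, 6))
  with_seed(config$seed + 2L, {
    mk <- function(i) {
      b <- veg * sig$veg[i] + bare * sig$bare[i] + water * sig$water[i]
      # noise truncated at 2.5 sigma so the painted index signatures stay
      # inside their declared bands by construction
      eps <- matrix(stats::rnorm(nr * nc, 0, config$reflectance_noise),
                    nr, nc)
      lim <- 2.5 * config$reflectance_noise
      pmax(b + pmin(pmax(eps, -lim), lim), 0)
    }
    blue <- mk(1); green <- mk(2); red <- mk(3); nir <- mk(4); swir <- mk(5)
    scl <- veg * 4 + bare * 5 + water * 6
    cloud <- matrix(FALSE, nr, nc)
    if (config$cloud_fraction > 0) {
      n_cloud_rows <- max(1L, round(config$cloud_fraction * nr))
      cloud[seq_len(n_cloud_rows), ] <- TRUE
      scl[cloud] <- 9
    }
    lay <- function(v, var) raster_layer(g, v, var, "LOCAL", date)
    list(bands = band_set(blue = lay(blue, "BLUE"),
                          green = lay(green, "GREEN"),
                          red = lay(red, "RED"), nir = lay(nir, "NIR"),
                          swir = lay(swir, "SWIR"), date = date),
         scl = lay(scl, "SCL"),
         truth_masks = list(vegetation = veg, bare = bare, water = water,
                            cloud = cloud))
  })
}

#' Synthetic station network in provider dialects
#'
#' Scatters stations uniformly over the fixture extent, samples daily
#' precipitation and temperature records from smooth truth fields plus
#' noise, and re-serializes the same records into two distinct provider
#' dialects (different column names, date formats and unit scalings), each
#' with its [provider_mapping()]. Harmonizing either dialect must recover
#' the common record set.
#'
#' @param config A [fixture_config()].
#' @param dates Vector of observation dates.
#' @param prec_truth Function `(x, y, day_index) -> mm/day` (default: a
#'   smooth positive field).
#' @param noise_sd Record noise SD (mm for precipitation, degC for
#'   temperature).
#' @return List with `stations`, `records` (ground-truth harmonized set),
#'   `tables` (named list of dialects, each `list(provider, table,
#'   mapping)`) and `prec_truth`.
#' @export
make_station_network <- function(config,
                                 dates = as.Date("2020-07-01") + 0:9,
                                 prec_truth = NULL, noise_sd = 0) {
  e <- grid_extent(fixture_grid(config))
  if (is.null(prec_truth))
    prec_truth <- function(x, y, day) {
      5 + 4 * sin(2 * pi * (x - e[["xmin"]]) / (e[["xmax"]] - e[["xmin"]])) +
        3 * cos(2 * pi * (y - e[["ymin"]]) / (e[["ymax"]] - e[["ymin"]])) +
        0.2 * day
    }
  with_seed(config$seed + 3L, {
    n <- config$n_stations
    stations <- data.frame(
      station_id = sprintf("ST%03d", seq_len(n)),
      provider = rep(c("AGENCY-A", "AGENCY-B"), length.out = n),
      x = stats::runif(n, e[["xmin"]], e[["xmax"]]),
      y = stats::runif(n, e[["ymin"]], e[["ymax"]]),
      elevation = stats::runif(n, 0, config$dem_relief),
      active_from = as.Date("2008-01-01"),
      active_to = as.Date("2030-12-31"), stringsAsFactors = FALSE)
    recs <- list()
    for (d in seq_along(dates)) {
      prec <- pmax(prec_truth(stations$x, stations$y, d) +
                     stats::rnorm(n, 0, noise_sd), 0)
      tmd <- 22 - 0.005 * stations$elevation +
        stats::rnorm(n, 0, noise_sd)
      recs[[d]] <- data.frame(
        station_id = rep(stations$station_id, 4L),
        date = dates[d],
        variable = rep(c("PREC", "TMN2", "TMD2", "TMX2"), each = n),
        value = round(c(prec, tmd - 4, tmd, tmd + 5), 1),
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    wide <- stats::reshape(records, idvar = c("station_id", "date"),
                           timevar = "variable", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    table_a <- data.frame(
      stn = wide$station_id,
      data = format(wide$date, "%d/%m/%Y"),
      pioggia = wide$PREC, tmin = wide$TMN2, tmed = wide$TMD2,
      tmax = wide$TMX2, stringsAsFactors = FALSE)
    mapping_a <- provider_mapping(
      station_col = "stn", date_col = "data", date_format = "%d/%m/%Y",
      value_cols = list(
        pioggia = list(variable = "PREC"),
        tmin = list(variable = "TMN2"),
        tmed = list(variable = "TMD2"),
        tmax = list(variable = "TMX2")))
    table_b <- data.frame(
      station_code = wide$station_id,
      obs_date = format(wide$date, "%Y-%m-%d"),
      rr10 = round(wide$PREC * 10), tn10 = round(wide$TMN2 * 10),
      tm10 = round(wide$TMD2 * 10), tx10 = round(wide$TMX2 * 10),
      stringsAsFactors = FALSE)
    mapping_b <- provider_mapping(
      station_col = "station_code", date_col = "obs_date",
      date_format = "%Y-%m-%d",
      value_cols = list(
        rr10 = list(variable = "PREC", scale = 0.1),
        tn10 = list(variable = "TMN2", scale = 0.1),
        tm10 = list(variable = "TMD2", scale = 0.1),
        tx10 = list(variable = "TMX2", scale = 0.1)))
    list(stations = stations, records = records,
         tables = list(
           `AGENCY-A` = list(provider = "AGENCY-A", table = table_a,
                             mapping = mapping_a),
           `AGENCY-B` = list(provider = "AGENCY-B", table = table_b,
                             mapping = mapping_b)),
         prec_truth = prec_truth)
  })
}
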