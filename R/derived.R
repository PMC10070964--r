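# Derived epidemiological covariates: growing degree days, De Martonne
# aridity, rainy-day counts, windowed variability, the 19 bioclimatic
# variables, and zonal land-cover percentages.

#' Daily climate series for one pixel or station
#'
#' @param date Vector of Dates.
#' @param tmin,tmax,tmean Daily temperatures in degC (any may be `NULL`;
#'   `tmean` defaults to the tmin/tmax midpoint where both exist).
#' @param prec Daily precipitation in mm/day (>= 0).
#' @return A data frame of class `daily_climate`.
#' @export
daily_climate <- function(date, tmin = NULL, tmax = NULL, tmean = NULL,
                          prec = NULL) {
  n <- length(date)
  pick <- function(v) if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
  out <- data.frame(date = as.Date(date), tmin = pick(tmin),
                    tmax = pick(tmax), tmean = pick(tmean),
                    prec = pick(prec))
  mid <- is.na(out$tmean) & !is.na(out$tmin) & !is.na(out$tmax)
  out$tmean[mid] <- (out$tmin[mid] + out$tmax[mid]) / 2
  if (any(out$prec < 0, na.rm = TRUE))
    stop("precipitation must be non-negative", call. = FALSE)
  bad <- !is.na(out$tmin) & !is.na(out$tmax) & out$tmin > out$tmax
  if (any(bad))
    stop("tmin exceeds tmax on some days", call. = FALSE)
  class(out) <- c("daily_climate", "data.frame")
  out
}

#' Growing degree days
#'
#' Accumulated thermal units above a base temperature:
#' `sum over days of max(0, (tmax + tmin)/2 - t_base)`. Days with a missing
#' tmin or tmax are skipped and their count reported as attribute
#' `"n_missing"`. GDD is additive over partitioned date ranges.
#'
#' @param series A [daily_climate()].
#' @param t_base Base temperature in degC (default 10).
#' @param from,to Inclusive date range (default: whole series).
#' @return Degree-days (degC day), with attribute `n_missing`.
#' @examples
#' s <- daily_climate(as.Date("2020-06-01") + 0:9,
#'                    tmin = rep(10, 10), tmax = rep(20, 10))
#' gdd(s, t_base = 10)  # 50
#' @export
gdd <- function(series, t_base = 10, from = min(series$date),
                to = max(series$date)) {
  sel <- series[series$date >= as.Date(from) & series$date <= as.Date(to), ]
  if (!nrow(sel)) stop("empty period", call. = FALSE)
  ok <- !is.na(sel$tmin) & !is.na(sel$tmax)
  out <- sum(pmax(0, (sel$tmax[ok] + sel$tmin[ok]) / 2 - t_base))
  attr(out, "n_missing") <- sum(!ok)
  out
}

#' De Martonne aridity index
#'
#' Annual form `P / (T + 10)` with `P` the annual precipitation (mm) and
#' `T` the annual mean temperature (degC); low values flag drought-prone
#' habitats. The monthly form `12 p / (t + 10)` is exposed via
#' `monthly = TRUE`. Temperatures at or below -10 degC (the pole of the
#' formula) yield `NA`.
#'
#' @param prec Precipitation total, mm (annual, or monthly when
#'   `monthly = TRUE`).
#' @param temp Mean temperature, degC.
#' @param monthly Use the monthly variant.
#' @return Aridity index (vectorized).
#' @examples
#' de_martonne(600, 20)  # 20
#' @export
de_martonne <- function(prec, temp, monthly = FALSE) {
  out <- ifelse(temp > -10,
                (if (monthly) 12 else 1) * prec / (temp + 10), NA_real_)
  out[is.na(temp) | is.na(prec)] <- NA_real_
  out
}

#' Count rainy days
#'
#' Days whose precipitation meets the threshold; the comparison is
#' inclusive (`>=`) by default and configurable. Missing days are skipped.
#'
#' @param series A [daily_climate()].
#' @param threshold Precipitation threshold in mm (default 1).
#' @param from,to Inclusive date range (default: whole series).
#' @param strict Use a strictly-greater comparison instead.
#' @return Integer count of qualifying days.
#' @export
rainy_days <- function(series, threshold = 1, from = min(series$date),
                       to = max(series$date), strict = FALSE) {
  sel <- series[series$date >= as.Date(from) & series$date <= as.Date(to), ]
  if (!nrow(sel)) stop("empty period", call. = FALSE)
  p <- sel$prec[!is.na(sel$prec)]
  if (strict) sum(p > threshold) else sum(p >= threshold)
}

#' Per-cell variability of a raster time series
#'
#' Sample standard deviation (n - 1 denominator) and excess (Fisher)
#' kurtosis of each cell across the stack. Cells with fewer than 2 valid
#' observations get nodata SD; kurtosis needs at least 4 observations and
#' nonzero variance.
#'
#' @param layers List of [raster_layer()]s on one grid.
#' @return List with `sd` and `kurtosis` [raster_layer()]s.
#' @export
windowed_variability <- function(layers) {
  if (!length(layers)) stop("empty layer sequence", call. = FALSE)
  g <- layers[[1]]$grid
  for (l in layers)
    if (!grids_identical(l$grid, g))
      stop("layers are on different grids", call. = FALSE)
  arr <- vapply(layers, function(l) l$values, layers[[1]]$values)
  dim(arr) <- c(g$n_rows * g$n_cols, length(layers))
  n <- rowSums(!is.na(arr))
  mu <- rowMeans(arr, na.rm = TRUE)
  dev <- arr - mu
  m2 <- rowSums(dev^2, na.rm = TRUE)
  sdv <- ifelse(n >= 2, sqrt(m2 / (n - 1)), NA_real_)
  m2n <- m2 / n
  m4n <- rowSums(dev^4, na.rm = TRUE) / n
  kur <- ifelse(n >= 4 & m2n > 1e-12, m4n / m2n^2 - 3, NA_real_)
  list(sd = raster_layer(g, matrix(sdv, g$n_rows, g$n_cols),
                         paste0(layers[[1]]$variable, "-SD"),
                         layers[[1]]$level),
       kurtosis = raster_layer(g, matrix(kur, g$n_rows, g$n_cols),
                               paste0(layers[[1]]$variable, "-KURT"),
                               layers[[1]]$level))
}

#' Monthly climate normal for one pixel or zone
#'
#' @param tmin,tmax 12 monthly mean temperatures, degC (January first).
#' @param prec 12 monthly precipitation totals, mm.
#' @param tmean Optional 12 monthly mean temperatures; defaults to the
#'   tmin/tmax midpoint.
#' @return An object of class `monthly_climate`.
#' @export
monthly_climate <- function(tmin, tmax, prec, tmean = NULL) {
  if (length(tmin) != 12L || length(tmax) != 12L || length(prec) != 12L)
    stop(sprintf("need exactly 12 months (got %d/%d/%d)", length(tmin),
                 length(tmax), length(prec)), call. = FALSE)
  miss <- which(is.na(tmin) | is.na(tmax) | is.na(prec))
  if (length(miss))
    stop(sprintf("incomplete months: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (any(prec < 0)) stop("monthly precipitation must be >= 0",
                          call. = FALSE)
  if (is.null(tmean)) tmean <- (tmin + tmax) / 2
  structure(list(tmin = as.numeric(tmin), tmax = as.numeric(tmax),
                 tmean = as.numeric(tmean), prec = as.numeric(prec)),
            class = "monthly_climate")
}

# All 12 wrap-around quarters (3 consecutive calendar months), Jan-start
# first; ties between quarters are broken by the earliest start month.
quarter_members <- function() {
  lapply(1:12, function(m) ((m - 1):(m + 1) - 1) %% 12 + 1)
}

#' The 19 bioclimatic variables
#'
#' Standard annual bioclimatic summary of a 12-month climate: annual trends
#' (BIO1, BIO12), seasonality (BIO4, BIO15), extremes (BIO5, BIO6, BIO13,
#' BIO14) and quarter statistics (BIO8-BIO11, BIO16-BIO19), where a quarter
#' is any 3 consecutive calendar months with wrap-around and ties go to the
#' earliest quarter. BIO3 is `NA` when the annual range BIO7 is zero; BIO15
#' uses the conventional `mean + 1` denominator safeguard.
#'
#' @param monthly A [monthly_climate()].
#' @return Named numeric vector `BIO1` .. `BIO19`.
#' @examples
#' bioclim(monthly_climate(rep(10, 12), rep(10, 12), rep(50, 12)))
#' @export
bioclim <- function(monthly) {
  stopifnot(inherits(monthly, "monthly_climate"))
  tmin <- monthly$tmin; tmax <- monthly$tmax
  tavg <- monthly$tmean; prec <- monthly$prec
  q <- quarter_members()
  qt <- vapply(q, function(m) mean(tavg[m]), numeric(1))
  qp <- vapply(q, function(m) sum(prec[m]), numeric(1))
  bio5 <- max(tmax); bio6 <- min(tmin)
  bio7 <- bio5 - bio6
  bio2 <- mean(tmax - tmin)
  wetq <- which.max(qp); dryq <- which.min(qp)
  warmq <- which.max(qt); coldq <- which.min(qt)
  c(BIO1 = mean(tavg),
    BIO2 = bio2,
    BIO3 = if (bio7 > 0) 100 * bio2 / bio7 else NA_real_,
    BIO4 = 100 * stats::sd(tavg),
    BIO5 = bio5, BIO6 = bio6, BIO7 = bio7,
    BIO8 = qt[wetq], BIO9 = qt[dryq],
    BIO10 = qt[warmq], BIO11 = qt[coldq],
    BIO12 = sum(prec),
    BIO13 = max(prec), BIO14 = min(prec),
    BIO15 = 100 * stats::sd(prec) / (1 + mean(prec)),
    BIO16 = qp[wetq], BIO17 = qp[dryq],
    BIO18 = qp[warmq], BIO19 = qp[coldq])
}

#' Bioclimatic variables of a monthly raster stack
#'
#' Applies [bioclim()] cell-wise to 12-month stacks of monthly minimum /
#' maximum temperature and precipitation, producing one layer per
#' bioclimatic variable (19 layers per year).
#'
#' @param tmin,tmax,prec Lists of 12 monthly [raster_layer()]s each
#'   (January first), on one shared grid.
#' @return Named list of 19 [raster_layer()]s, `BIO1` .. `BIO19`.
#' @export
bioclim_layers <- function(tmin, tmax, prec) {
  if (length(tmin) != 12L || length(tmax) != 12L || length(prec) != 12L)
    stop("need 12 monthly layers per variable", call. = FALSE)
  g <- tmin[[1]]$grid
  stack <- function(ls) vapply(ls, function(l) {
    if (!grids_identical(l$grid, g))
      stop("monthly layers are on different grids", call. = FALSE)
    as.vector(l$values)
  }, numeric(g$n_rows * g$n_cols))
  tn <- stack(tmin); tx <- stack(tmax); pr <- stack(prec)
  ncell <- nrow(tn)
  out <- matrix(NA_real_, ncell, 19L)
  complete <- rowSums(is.na(tn) | is.na(tx) | is.na(pr)) == 0L
  for (i in which(complete))
    out[i, ] <- bioclim(monthly_climate(tn[i, ], tx[i, ], pr[i, ]))
  res <- lapply(seq_len(19L), function(j)
    raster_layer(g, matrix(out[, j], g$n_rows, g$n_cols),
                 paste0("BIO", j), tmin[[1]]$level))
  names(res) <- paste0("BIO", seq_len(19L))
  res
}

#' Monthly aggregates from daily layers
#'
#' Per-cell monthly mean (temperature-like variables) or monthly sum
#' (precipitation) of a list of daily layers; cells observed on fewer than
#' `min_frac` of the month's days are nodata.
#'
#' @param layers List of daily [raster_layer()]s with timestamps inside one
#'   calendar month.
#' @param fun `"mean"` or `"sum"`.
#' @param min_frac Minimum fraction of days a cell must be observed
#'   (default 0.8, i.e. at most 20 % missing).
#' @return One [raster_layer()] timestamped at the first of the month.
#' @export
monthly_aggregate <- function(layers, fun = c("mean", "sum"),
                              min_frac = 0.8) {
  fun <- match.arg(fun)
  if (!length(layers)) stop("empty layer list", call. = FALSE)
  g <- layers[[1]]$grid
  ts <- as.Date(vapply(layers, function(l) as.character(l$timestamp),
                       character(1)))
  mon <- unique(format(ts, "%Y-%m"))
  if (length(mon) != 1L)
    stop("layers span more than one calendar month", call. = FALSE)
  first <- as.Date(paste0(mon, "-01"))
  ndays <- as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1,
                             "%d"))
  sums <- matrix(0, g$n_rows, g$n_cols)
  cnts <- matrix(0L, g$n_rows, g$n_cols)
  for (l in layers) {
    if (!grids_identical(l$grid, g))
      stop("layers are on different grids", call. = FALSE)
    ok <- !is.na(l$values)
    sums[ok] <- sums[ok] + l$values[ok]
    cnts <- cnts + ok
  }
  out <- if (fun == "mean") sums / cnts else sums
  out[cnts < min_frac * ndays] <- NA_real_
  raster_layer(g, out, layers[[1]]$variable, layers[[1]]$level, first)
}

#' Zonal land-cover percentages
#'
#' For every zone, the percentage of its valid class cells in each class.
#' Percentages within a zone sum to 100; a zone with no valid cell is
#' reported with an empty breakdown (`n_cells = 0`).
#'
#' @param classes Categorical [raster_layer()] of integer class codes.
#' @param zones [raster_layer()] of integer zone ids on the same grid.
#' @return Data frame with `zone`, `class`, `n_cells`, `percent`.
#' @export
landcover_percent <- function(classes, zones) {
  if (!grids_identical(classes$grid, zones$grid))
    stop("class and zone rasters are on different grids", call. = FALSE)
  z <- as.vector(zones$values)
  k <- as.vector(classes$values)
  out <- data.frame(zone = integer(), class = integer(),
                    n_cells = integer(), percent = numeric())
  for (zid in sort(unique(z[!is.na(z)]))) {
    kk <- k[!is.na(z) & z == zid]
    kk <- kk[!is.na(kk)]
    if (!length(kk)) {
      out <- rbind(out, data.frame(zone = zid, class = NA_integer_,
                                   n_cells = 0L, percent = NA_real_))
      next
    }
    tab <- table(kk)
    out <- rbind(out, data.frame(
      zone = zid, class = as.integer(names(tab)),
      n_cells = as.integer(tab),
      percent = 100 * as.integer(tab) / length(kk)))
  }
  rownames(out) <- NULL
  out
}
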