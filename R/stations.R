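# Harmonization of heterogeneous provider station tables, QA cleaning,
# querying, and spline interpolation of daily precipitation to the grid.

#' Codified meteorological variables
#'
#' Daily maximum / mean / minimum air temperature at 2 m (`TMX2`, `TMD2`,
#' `TMN2`, degC), daily cumulative precipitation (`PREC`, mm/day), and
#' maximum / mean / minimum relative humidity (`UMX2`, `UMD2`, `UMN2`, %).
#'
#' @return Character vector of the recognized variable codes.
#' @export
met_variables <- function() {
  c("TMX2", "TMD2", "TMN2", "PREC", "UMX2", "UMD2", "UMN2")
}

#' Declare a provider table dialect
#'
#' Each source agency ships daily observations in its own table layout;
#' a mapping declares how to read it: which columns hold the station id and
#' the date, the date format, and for each value column the target variable
#' code plus the affine unit conversion (`value * scale + offset`, e.g.
#' scale 0.1 for tenths of a degree).
#'
#' @param station_col,date_col Raw column names.
#' @param date_format `strptime` format of the date column.
#' @param value_cols Named list: raw column name -> list(`variable`,
#'   optional `scale`, optional `offset`).
#' @param na_strings Strings treated as missing values.
#' @return An object of class `provider_mapping`.
#' @export
provider_mapping <- function(station_col, date_col, date_format, value_cols,
                             na_strings = c("", "NA", "-999", "-999.0")) {
  for (vc in value_cols)
    if (!(vc$variable %in% met_variables()))
      stop(sprintf("unknown variable code '%s'", vc$variable), call. = FALSE)
  structure(list(station_col = station_col, date_col = date_col,
                 date_format = date_format, value_cols = value_cols,
                 na_strings = na_strings),
            class = "provider_mapping")
}

empty_records <- function() {
  data.frame(station_id = character(), date = as.Date(character()),
              variable = character(), value = numeric(),
              stringsAsFactors = FALSE)
}

#' Harmonize a provider table into the common daily schema
#'
#' Converts one provider-dialect table into long-format harmonized records
#' (station, date, variable code, value in standard units). Rows whose date
#' cannot be parsed, and cells that are missing or non-numeric, are rejected
#' with a reason rather than silently dropped.
#'
#' @param raw_rows Data frame in the provider's layout.
#' @param provider Provider tag (recorded on rejections).
#' @param mapping A [provider_mapping()] for this provider.
#' @return List with `records` (harmonized data frame: `station_id`,
#'   `date`, `variable`, `value`) and `rejected` (data frame with `row`,
#'   `column`, `reason`).
#' @export
harmonize_provider_table <- function(raw_rows, provider, mapping) {
  if (!inherits(mapping, "provider_mapping"))
    stop("`mapping` must be a provider_mapping", call. = FALSE)
  for (col in c(mapping$station_col, mapping$date_col,
                names(mapping$value_cols)))
    if (!(col %in% names(raw_rows)))
      stop(sprintf("provider '%s': column '%s' absent from table",
                   provider, col), call. = FALSE)
  rejected <- data.frame(row = integer(), column = character(),
                         reason = character(), stringsAsFactors = FALSE)
  if (nrow(raw_rows) == 0L)
    return(list(records = empty_records(), rejected = rejected))
  dates <- as.Date(strptime(as.character(raw_rows[[mapping$date_col]]),
                            mapping$date_format))
  recs <- list()
  for (col in names(mapping$value_cols)) {
    vc <- mapping$value_cols[[col]]
    scale <- if (is.null(vc$scale)) 1 else vc$scale
    offset <- if (is.null(vc$offset)) 0 else vc$offset
    raw <- as.character(raw_rows[[col]])
    missing <- is.na(raw) | raw %in% mapping$na_strings
    num <- suppressWarnings(as.numeric(raw))
    badnum <- !missing & is.na(num)
    baddate <- is.na(dates)
    keep <- !missing & !badnum & !baddate
    if (any(baddate & !missing))
      rejected <- rbind(rejected, data.frame(
        row = which(baddate & !missing), column = col,
        reason = "bad-date", stringsAsFactors = FALSE))
    if (any(missing))
      rejected <- rbind(rejected, data.frame(
        row = which(missing), column = col, reason = "missing-value",
        stringsAsFactors = FALSE))
    if (any(badnum))
      rejected <- rbind(rejected, data.frame(
        row = which(badnum), column = col, reason = "bad-value",
        stringsAsFactors = FALSE))
    if (any(keep))
      recs[[col]] <- data.frame(
        station_id = as.character(raw_rows[[mapping$station_col]][keep]),
        date = dates[keep], variable = vc$variable,
        value = num[keep] * scale + offset, stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else empty_records()
  rownames(records) <- NULL
  list(records = records, rejected = rejected)
}

#' Default record-level quality rules
#'
#' Plausibility ranges per variable family (temperature `[-50, 50]` degC,
#' precipitation `[0, 1000]` mm/day, humidity `[0, 100]` %), plus the
#' per-station-day ordering constraint TMN2 <= TMD2 <= TMX2.
#'
#' @return Named list of rule parameters.
#' @export
qa_rules <- function() {
  list(temp_range = c(-50, 50), prec_range = c(0, 1000),
       hum_range = c(0, 100), enforce_ordering = TRUE)
}

#' Quality-clean harmonized records
#'
#' Applies, in order: collapse of exact duplicate records (identical
#' key and value; surplus copies are reported, one survives), rejection of
#' conflicting duplicates (same station/date/variable, different values:
#' all copies rejected), plausibility ranges, and the temperature ordering
#' rule (a violating TMN2/TMD2/TMX2 triple is rejected whole). Every input
#' record lands in exactly one of the two outputs, so
#' `nrow(accepted) + nrow(rejected) == nrow(records)`.
#'
#' @param records Harmonized records data frame.
#' @param rules Rule list, see [qa_rules()].
#' @return List with `accepted` (records) and `rejected` (records plus a
#'   `reason` column).
#' @export
qa_clean <- function(records, rules = qa_rules()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (n) {
    key <- paste(records$station_id, records$date, records$variable,
                 sep = "|")
    dupkey <- unique(key[duplicated(key)])
    conflict <- dupkey[vapply(dupkey, function(k)
      length(unique(records$value[key == k])) > 1L, logical(1))]
    reason[key %in% conflict] <- "duplicate-conflict"
    keyval <- paste(key, records$value, sep = "|")
    reason[is.na(reason) & duplicated(keyval)] <- "duplicate-collapsed"
    rng <- function(vars, lim)
      records$variable %in% vars &
        (records$value < lim[1] | records$value > lim[2])
    out_of_range <- rng(c("TMX2", "TMD2", "TMN2"), rules$temp_range) |
      rng("PREC", rules$prec_range) |
      rng(c("UMX2", "UMD2", "UMN2"), rules$hum_range)
    reason[is.na(reason) & out_of_range] <- "range"
    if (isTRUE(rules$enforce_ordering)) {
      alive <- is.na(reason) &
        records$variable %in% c("TMX2", "TMD2", "TMN2")
      if (any(alive)) {
        tmp <- records[alive, c("station_id", "date", "variable", "value")]
        wide <- stats::reshape(tmp, idvar = c("station_id", "date"),
                               timevar = "variable", direction = "wide")
        for (v in c("value.TMN2", "value.TMD2", "value.TMX2"))
          if (is.null(wide[[v]])) wide[[v]] <- NA_real_
        bad <- !is.na(wide$value.TMN2) & !is.na(wide$value.TMD2) &
          !is.na(wide$value.TMX2) &
          !(wide$value.TMN2 <= wide$value.TMD2 &
              wide$value.TMD2 <= wide$value.TMX2)
        badkey <- paste(wide$station_id, wide$date)[bad]
        hit <- alive & paste(records$station_id, records$date) %in% badkey
        reason[hit] <- "ordering"
      }
    }
  }
  accepted <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(accepted) <- NULL; rownames(rejected) <- NULL
  list(accepted = accepted, rejected = rejected)
}

#' Assemble a station store
#'
#' Flat-table store of the georeferenced station registry plus their
#' harmonized daily records.
#'
#' @param stations Data frame with `station_id`, `provider`, `x`, `y`
#'   (UTM32N meters), `elevation` (m), `active_from`, `active_to` (Dates).
#' @param records Harmonized (and ideally [qa_clean()]ed) records.
#' @return An object of class `station_store`.
#' @export
station_store <- function(stations, records) {
  need <- c("station_id", "x", "y")
  if (!all(need %in% names(stations)))
    stop("station registry needs station_id, x, y", call. = FALSE)
  if (any(stations$elevation < -10, na.rm = TRUE))
    stop("implausible station elevation (< -10 m)", call. = FALSE)
  structure(list(stations = stations, records = records),
            class = "station_store")
}

#' Query one station's series for one variable
#'
#' Returns the records sorted by date; gaps are preserved, nothing is
#' imputed.
#'
#' @param store A [station_store()].
#' @param variable Variable code, see [met_variables()].
#' @param station_id Station identifier; unknown ids are an error.
#' @param from,to Inclusive date range (default: unbounded).
#' @return Data frame of records sorted by date.
#' @export
query_station_series <- function(store, variable, station_id,
                                 from = as.Date("1000-01-01"),
                                 to = as.Date("3000-01-01")) {
  if (!(station_id %in% store$stations$station_id))
    stop(sprintf("unknown station '%s'", station_id), call. = FALSE)
  r <- store$records
  r <- r[r$station_id == station_id & r$variable == variable &
           r$date >= as.Date(from) & r$date <= as.Date(to), , drop = FALSE]
  r <- r[order(r$date), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Interpolate daily station precipitation to a grid
#'
#' Fits a regularized thin-plate spline (tension/smoothing configurable,
#' exact at stations when `smoothing = 0`) to the stations reporting
#' precipitation on one date and evaluates it on the target grid. Negative
#' interpolated values are floored at zero.
#'
#' @param day_records Records for a single date (only `PREC` rows are used).
#' @param stations Station registry data frame (`station_id`, `x`, `y`).
#' @param target Target [grid_spec()] (the 1 km local master grid).
#' @param tension,smoothing Spline parameters, see [tps_fit()].
#' @param min_stations Minimum reporting stations required (default 5).
#' @return A `PREC` [raster_layer()] on `target`.
#' @export
interpolate_precipitation <- function(day_records, stations, target,
                                      tension = 40, smoothing = 0.1,
                                      min_stations = 5L) {
  r <- day_records[day_records$variable == "PREC", , drop = FALSE]
  dates <- unique(r$date)
  if (length(dates) > 1L)
    stop("records span more than one date", call. = FALSE)
  idx <- match(r$station_id, stations$station_id)
  if (anyNA(idx))
    stop("records reference stations absent from the registry",
         call. = FALSE)
  if (nrow(r) < min_stations)
    stop(sprintf("only %d station(s) report precipitation on %s (need %d)",
                 nrow(r), if (length(dates)) format(dates) else "?",
                 min_stations), call. = FALSE)
  fit <- tps_fit(stations$x[idx], stations$y[idx], r$value,
                 tension = tension, smoothing = smoothing)
  ctr <- grid_centers(target)
  px <- rep(ctr$x, each = target$n_rows)
  py <- rep(ctr$y, times = target$n_cols)
  surf <- pmax(tps_predict(fit, px, py), 0)
  raster_layer(target, matrix(surf, target$n_rows, target$n_cols),
               "PREC", "LOCAL", dates[1])
}
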