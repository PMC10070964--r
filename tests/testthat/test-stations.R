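simple_mapping <- function() {
  provider_mapping(
    station_col = "stn", date_col = "data", date_format = "%d/%m/%Y",
    value_cols = list(tmax = list(variable = "TMX2"),
                      pioggia = list(variable = "PREC")))
}

test_that("provider tables harmonize into the common schema", {
  raw <- data.frame(stn = c("S1", "S2"), data = c("31/12/2021", "01/01/2022"),
                    tmax = c("12.5", "3.0"), pioggia = c("0", "14.2"),
                    stringsAsFactors = FALSE)
  out <- harmonize_provider_table(raw, "AGENCY-A", simple_mapping())
  expect_equal(nrow(out$records), 4)
  r <- out$records[out$records$variable == "TMX2" &
                     out$records$station_id == "S1", ]
  expect_equal(r$date, as.Date("2021-12-31"))
  expect_equal(r$value, 12.5)
  expect_equal(nrow(out$rejected), 0)
})

test_that("unit conversions are applied and round-trip losslessly", {
  raw <- data.frame(stn = "S1", data = "15/06/2020", tmax = "235",
                    pioggia = "120", stringsAsFactors = FALSE)
  mapping <- provider_mapping(
    station_col = "stn", date_col = "data", date_format = "%d/%m/%Y",
    value_cols = list(tmax = list(variable = "TMX2", scale = 0.1),
                      pioggia = list(variable = "PREC", scale = 0.1)))
  out <- harmonize_provider_table(raw, "AGENCY-B", mapping)
  expect_equal(out$records$value[out$records$variable == "TMX2"], 23.5)
  expect_equal(out$records$value[out$records$variable == "PREC"], 12)
})

test_that("bad rows are rejected with reasons, not dropped", {
  raw <- data.frame(stn = c("S1", "S2", "S3"),
                    data = c("31/12/2021", "not-a-date", "01/06/2021"),
                    tmax = c("NA", "10", "abc"),
                    pioggia = c("5", "3", "1"), stringsAsFactors = FALSE)
  out <- harmonize_provider_table(raw, "AGENCY-A", simple_mapping())
  expect_setequal(out$rejected$reason[out$rejected$column == "tmax"],
                  c("missing-value", "bad-date", "bad-value"))
  # the valid precipitation cells of rows 1 and 3 survive
  expect_equal(sum(out$records$variable == "PREC"), 2)
  empty <- harmonize_provider_table(raw[0, ], "AGENCY-A", simple_mapping())
  expect_equal(nrow(empty$records), 0)
  expect_error(harmonize_provider_table(raw, "AGENCY-A",
    provider_mapping("missing", "data", "%d/%m/%Y",
                     list(tmax = list(variable = "TMX2")))),
    "absent from table")
})

recs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(station_id = r[[1]], date = as.Date(r[[2]]),
               variable = r[[3]], value = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)))
}

test_that("qa_clean enforces ranges, ordering and duplicate policy", {
  good <- recs(list("S1", "2020-06-01", "TMN2", 5),
               list("S1", "2020-06-01", "TMD2", 10),
               list("S1", "2020-06-01", "TMX2", 15))
  out <- qa_clean(good)
  expect_equal(nrow(out$accepted), 3)
  expect_equal(nrow(out$rejected), 0)

  inverted <- recs(list("S1", "2020-06-01", "TMN2", 15),
                   list("S1", "2020-06-01", "TMD2", 10),
                   list("S1", "2020-06-01", "TMX2", 5))
  out2 <- qa_clean(inverted)
  expect_equal(nrow(out2$accepted), 0)
  expect_true(all(out2$rejected$reason == "ordering"))

  bad_range <- recs(list("S1", "2020-06-01", "PREC", -3),
                    list("S2", "2020-06-01", "TMX2", 72),
                    list("S3", "2020-06-01", "UMD2", 130))
  out3 <- qa_clean(bad_range)
  expect_equal(nrow(out3$accepted), 0)
  expect_true(all(out3$rejected$reason == "range"))

  dup <- recs(list("S1", "2020-06-01", "PREC", 4),
              list("S1", "2020-06-01", "PREC", 4),
              list("S2", "2020-06-01", "PREC", 1),
              list("S2", "2020-06-01", "PREC", 2))
  out4 <- qa_clean(dup)
  expect_equal(nrow(out4$accepted), 1)  # one survivor of the exact pair
  expect_setequal(out4$rejected$reason,
                  c("duplicate-collapsed", "duplicate-conflict"))
  expect_equal(sum(out4$rejected$reason == "duplicate-conflict"), 2)
})

test_that("qa_clean conserves records and is idempotent", {
  set.seed(14)
  net <- make_station_network(fixture_config(seed = 14, n_stations = 10))
  r <- net$records
  r$value[sample(nrow(r), 5)] <- 999   # implant range violations
  out <- qa_clean(r)
  expect_equal(nrow(out$accepted) + nrow(out$rejected), nrow(r))
  again <- qa_clean(out$accepted)
  expect_equal(nrow(again$rejected), 0)
  expect_equal(again$accepted, out$accepted)
})

test_that("station series queries sort by date and preserve gaps", {
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  keep <- !(dates >= as.Date("2021-03-10") & dates <= as.Date("2021-03-19"))
  records <- data.frame(station_id = "S1", date = dates[keep],
                        variable = "PREC",
                        value = seq_len(sum(keep)) %% 7,
                        stringsAsFactors = FALSE)
  stations <- data.frame(station_id = "S1", provider = "A", x = 650000,
                         y = 5100000, elevation = 100,
                         stringsAsFactors = FALSE)
  store <- station_store(stations, records)
  full <- query_station_series(store, "PREC", "S1")
  expect_equal(nrow(full), 355)  # 365 minus the 10-day gap
  expect_false(is.unsorted(full$date))
  out_of_range <- query_station_series(store, "PREC", "S1",
                                       from = "2025-01-01",
                                       to = "2025-12-31")
  expect_equal(nrow(out_of_range), 0)
  expect_error(query_station_series(store, "PREC", "NOPE"),
               "unknown station")
})

test_that("precipitation interpolation reproduces constants and stations", {
  set.seed(41)
  n <- 30
  stations <- data.frame(station_id = sprintf("S%02d", 1:n),
                         x = runif(n, 600000, 660000),
                         y = runif(n, 5100000, 5160000),
                         elevation = 0, stringsAsFactors = FALSE)
  target <- grid_spec("EPSG:32632", 600000, 5160000, 1000, 60, 60)
  day <- function(v) data.frame(station_id = stations$station_id,
                                date = as.Date("2020-06-01"),
                                variable = "PREC", value = v,
                                stringsAsFactors = FALSE)
  # constant field recovery with zero smoothing
  surf <- interpolate_precipitation(day(rep(6.5, n)), stations, target,
                                    smoothing = 0)
  expect_lt(max(abs(surf$values - 6.5)), 1e-6)
  # zero smoothing interpolates exactly: the fitted surface evaluated at
  # the station locations reproduces the station values
  vals <- runif(n, 0, 30)
  fit <- tps_fit(stations$x, stations$y, vals, smoothing = 0)
  expect_lt(max(abs(tps_predict(fit, stations$x, stations$y) - vals)), 0.1)
  surf2 <- interpolate_precipitation(day(vals), stations, target,
                                     smoothing = 0)
  expect_true(all(surf2$values >= 0))
  # and on a fine grid the station's own cell carries the station value
  fine <- grid_spec("EPSG:32632", 600000, 5160000, 100, 600, 600)
  surf3 <- interpolate_precipitation(day(vals), stations, fine,
                                     smoothing = 0)
  at_st <- envgrid:::sample_nearest(surf3, stations$x, stations$y)
  expect_lt(max(abs(at_st - vals)), 0.5)
  expect_error(interpolate_precipitation(day(vals)[1:3, ], stations, target),
               "need 5")
})

test_that("interpolation recovers a smooth field sampled at 100 stations", {
  set.seed(52)
  n <- 100
  stations <- data.frame(station_id = sprintf("S%03d", 1:n),
                         x = runif(n, 600000, 680000),
                         y = runif(n, 5080000, 5160000),
                         stringsAsFactors = FALSE)
  truth <- function(x, y)
    10 + 6 * sin((x - 600000) / 25000) + 4 * cos((y - 5080000) / 25000)
  target <- grid_spec("EPSG:32632", 600000, 5160000, 1000, 80, 80)
  day <- data.frame(station_id = stations$station_id,
                    date = as.Date("2020-06-01"), variable = "PREC",
                    value = truth(stations$x, stations$y),
                    stringsAsFactors = FALSE)
  surf <- interpolate_precipitation(day, stations, target, smoothing = 0)
  ctr <- grid_centers(target)
  want <- pmax(outer(ctr$y, ctr$x, function(y, x) truth(x, y)), 0)
  rmse <- sqrt(mean((surf$values - want)^2))
  expect_lt(rmse, 0.1 * diff(range(want)))
})
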