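test_that("growing degree days accumulate heat above the base", {
  s <- daily_climate(as.Date("2020-06-01") + 0:9,
                     tmin = rep(10, 10), tmax = rep(20, 10))
  expect_equal(as.numeric(gdd(s, t_base = 10)), 50)
  cold <- daily_climate(as.Date("2020-01-01") + 0:9,
                        tmin = rep(-5, 10), tmax = rep(3, 10))
  expect_equal(as.numeric(gdd(cold, t_base = 10)), 0)
  # a very low base reduces to the sum of daily means plus base * n
  set.seed(2)
  tmin <- runif(20, 0, 10); tmax <- tmin + runif(20, 0, 10)
  s2 <- daily_climate(as.Date("2020-06-01") + 0:19, tmin = tmin,
                      tmax = tmax)
  expect_equal(as.numeric(gdd(s2, t_base = -100)),
               sum((tmin + tmax) / 2) + 100 * 20)
  expect_error(gdd(s, from = "2021-01-01", to = "2021-02-01"),
               "empty period")
})

test_that("gdd is additive over partitioned periods and skips missing days", {
  set.seed(10)
  d <- as.Date("2020-04-01") + 0:59
  tmin <- runif(60, 2, 12); tmax <- tmin + runif(60, 1, 12)
  tmin[c(5, 40)] <- NA
  s <- daily_climate(d, tmin = tmin, tmax = tmax)
  whole <- gdd(s, 10)
  part <- gdd(s, 10, d[1], d[30])
  rest <- gdd(s, 10, d[31], d[60])
  expect_equal(as.numeric(whole), as.numeric(part) + as.numeric(rest))
  expect_equal(attr(whole, "n_missing"), 2)
})

test_that("the aridity index divides rainfall by shifted temperature", {
  expect_equal(de_martonne(600, 20), 20)
  expect_equal(de_martonne(0, 15), 0)
  expect_true(is.na(de_martonne(500, -10)))
  expect_true(is.na(de_martonne(500, -12)))
  # monthly variant scales to an annual equivalent
  expect_equal(de_martonne(50, 20, monthly = TRUE), 20)
})

test_that("rainy-day counts use an inclusive threshold and are monotone", {
  s <- daily_climate(as.Date("2020-06-01") + 0:4,
                     prec = c(0, 0.1, 1, 5, 0))
  expect_equal(rainy_days(s, 1), 2)
  expect_equal(rainy_days(s, 0), 5)
  expect_equal(rainy_days(s, 1, strict = TRUE), 1)
  dry <- daily_climate(as.Date("2020-06-01") + 0:4, prec = rep(0, 5))
  expect_equal(rainy_days(dry, 1), 0)
  set.seed(77)
  s2 <- daily_climate(as.Date("2020-06-01") + 0:99,
                      prec = rexp(100, 1 / 4))
  counts <- vapply(seq(0, 20, 0.5), function(th) rainy_days(s2, th),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("windowed variability computes sample SD and excess kurtosis", {
  g <- utm_grid(2, 2)
  mk <- function(v) raster_layer(g, v, "LST", "LOCAL")
  const <- windowed_variability(lapply(1:5, function(i) mk(3)))
  expect_equal(const$sd$values, matrix(0, 2, 2))
  expect_true(all(is.na(const$kurtosis$values)))  # zero variance
  two_pt <- windowed_variability(lapply(c(1, 1, -1, -1), mk))
  expect_equal(two_pt$sd$values[1, 1], 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(two_pt$kurtosis$values[1, 1], -2)
  set.seed(30)
  g1 <- utm_grid(1, 1)
  gauss <- windowed_variability(lapply(1:20000, function(i)
    raster_layer(g1, rnorm(1), "LST")))
  expect_lt(abs(gauss$kurtosis$values[1, 1]), 0.1)
  expect_equal(gauss$sd$values[1, 1], 1, tolerance = 0.05)
  # minimum-observation rules
  short <- windowed_variability(lapply(1:3, function(i)
    mk(matrix(rnorm(4), 2, 2))))
  expect_true(all(is.na(short$kurtosis$values)))
  expect_false(anyNA(short$sd$values))
  one <- windowed_variability(list(mk(1)))
  expect_true(all(is.na(one$sd$values)))
  expect_error(windowed_variability(list()), "empty")
})

test_that("a constant climate collapses the bioclim profile", {
  b <- bioclim(monthly_climate(rep(10, 12), rep(10, 12), rep(50, 12)))
  expect_length(b, 19)
  expect_equal(unname(b[c("BIO1", "BIO2", "BIO4", "BIO5", "BIO6", "BIO7")]),
               c(10, 0, 0, 10, 10, 0))
  expect_true(is.na(b[["BIO3"]]))
  expect_equal(unname(b[c("BIO12", "BIO13", "BIO14", "BIO15")]),
               c(600, 50, 50, 0))
  expect_error(monthly_climate(rep(10, 11), rep(10, 12), rep(50, 12)),
               "12 months")
  expect_error(monthly_climate(c(NA, rep(10, 11)), rep(10, 12), rep(50, 12)),
               "incomplete months: 1")
})

test_that("bioclim matches the brute-force quarter enumeration", {
  set.seed(19)
  for (i in 1:25) {
    tmin <- runif(12, -15, 12)
    tmax <- tmin + runif(12, 0.5, 15)
    prec <- runif(12, 0, 250)
    got <- bioclim(monthly_climate(tmin, tmax, prec))
    expect_equal(got, brute_bioclim(tmin, tmax, prec), tolerance = 1e-12)
  }
})

test_that("bioclim internal identities hold on randomized climates", {
  set.seed(23)
  for (i in 1:25) {
    tmin <- runif(12, -10, 10); tmax <- tmin + runif(12, 0, 12)
    prec <- runif(12, 0, 300)
    b <- bioclim(monthly_climate(tmin, tmax, prec))
    expect_equal(b[["BIO7"]], b[["BIO5"]] - b[["BIO6"]])
    expect_equal(b[["BIO13"]], max(prec))
    expect_gte(b[["BIO13"]], b[["BIO14"]])
    expect_gte(b[["BIO16"]], b[["BIO17"]])
    expect_gte(b[["BIO16"]], 3 * b[["BIO14"]])
    expect_equal(b[["BIO12"]], sum(prec))
  }
})

test_that("bioclim raster stacks agree with the scalar computation per cell", {
  set.seed(40)
  g <- utm_grid(4, 5, 1000)
  tmin <- lapply(1:12, function(m)
    raster_layer(g, matrix(runif(20, -5, 10), 4, 5), "TMIN"))
  tmax <- lapply(1:12, function(m)
    raster_layer(g, tmin[[m]]$values + matrix(runif(20, 1, 10), 4, 5),
                 "TMAX"))
  prec <- lapply(1:12, function(m)
    raster_layer(g, matrix(runif(20, 0, 200), 4, 5), "PREC"))
  layers <- bioclim_layers(tmin, tmax, prec)
  expect_length(layers, 19)
  expect_named(layers, paste0("BIO", 1:19))
  for (cell in c(1, 7, 20)) {
    b <- bioclim(monthly_climate(
      vapply(tmin, function(l) l$values[cell], numeric(1)),
      vapply(tmax, function(l) l$values[cell], numeric(1)),
      vapply(prec, function(l) l$values[cell], numeric(1))))
    got <- vapply(layers, function(l) l$values[cell], numeric(1))
    expect_equal(unname(got), unname(b))
  }
  # a cell with any missing month is nodata in every output layer
  tmin[[4]]$values[2, 2] <- NA
  layers2 <- bioclim_layers(tmin, tmax, prec)
  expect_true(all(vapply(layers2, function(l) is.na(l$values[2, 2]),
                         logical(1))))
})

test_that("monthly aggregation applies the missing-day rule", {
  g <- utm_grid(2, 2)
  days <- lapply(1:30, function(d) {
    v <- matrix(as.numeric(d), 2, 2)
    if (d <= 10) v[1, 1] <- NA  # cell observed on 20/30 days only (66 %)
    raster_layer(g, v, "PREC", "LOCAL", as.Date("2020-06-01") + d - 1)
  })
  m <- monthly_aggregate(days, "sum")
  expect_true(is.na(m$values[1, 1]))
  expect_equal(m$values[2, 2], sum(1:30))
  mm <- monthly_aggregate(days, "mean")
  expect_equal(mm$values[2, 2], mean(1:30))
  expect_equal(m$timestamp, as.Date("2020-06-01"))
  expect_error(monthly_aggregate(c(days, list(raster_layer(
    g, 1, "PREC", "LOCAL", as.Date("2020-07-01")))), "sum"),
    "more than one calendar month")
})

test_that("per-pixel derived statistics commute with cropping", {
  set.seed(61)
  g <- utm_grid(8, 8)
  layers <- lapply(1:6, function(i)
    raster_layer(g, matrix(rnorm(64), 8, 8), "NDVI", "LOCAL",
                 as.Date("2020-06-01") + i))
  e <- grid_extent(g)
  box <- c(xmin = e[["xmin"]] + 200, xmax = e[["xmax"]] - 100,
           ymin = e[["ymin"]] + 100, ymax = e[["ymax"]] - 300)
  full <- windowed_variability(layers)
  cropped <- windowed_variability(lapply(layers, crop_layer, extent = box))
  expect_layers_equal(cropped$sd, crop_layer(full$sd, box))
  expect_layers_equal(cropped$kurtosis, crop_layer(full$kurtosis, box))
})

test_that("zonal land-cover percentages count cells per class", {
  g <- utm_grid(4, 4)
  one_zone <- raster_layer(g, 1)
  forest <- raster_layer(g, 23)
  t1 <- landcover_percent(forest, one_zone)
  expect_equal(t1$percent, 100)
  expect_equal(t1$class, 23L)
  checker <- raster_layer(g, outer(1:4, 1:4, function(i, j)
    ifelse((i + j) %% 2 == 0, 1, 2)))
  t2 <- landcover_percent(checker, one_zone)
  expect_equal(t2$percent, c(50, 50))
  expect_equal(sum(t2$percent), 100, tolerance = 1e-9)
  # zone with no valid class cells gets an empty breakdown
  nocover <- raster_layer(g, matrix(NA_real_, 4, 4))
  t3 <- landcover_percent(nocover, one_zone)
  expect_equal(t3$n_cells, 0L)
  # multi-zone percentages each sum to 100
  zones <- raster_layer(g, outer(1:4, 1:4, function(i, j)
    ifelse(j <= 2, 1, 2)))
  t4 <- landcover_percent(checker, zones)
  expect_equal(as.numeric(tapply(t4$percent, t4$zone, sum)), c(100, 100))
})
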