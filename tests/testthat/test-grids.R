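test_that("snap_resolution honours registry targets and rounds otherwise", {
  expect_equal(snap_resolution(0.25, "deg", source = "EOBS"), 27000)
  expect_equal(snap_resolution(0.1, "deg", source = "GPM"), 10000)
  expect_equal(snap_resolution(1000), 1000)
  # half-up rounding on kilometers for unregistered products
  expect_equal(snap_resolution(1500), 2000)
  expect_equal(snap_resolution(1499.9), 1000)
  expect_equal(snap_resolution(250), 1000)  # floored at 1 km
  expect_error(snap_resolution(0.25, "deg", source = "NOPE"),
               "unknown product source")
  expect_error(snap_resolution(-1), "positive")
})

test_that("level extents nest and master grids sit on the declared lattice", {
  loc <- level_info("LOCAL"); cty <- level_info("COUNTRY")
  expect_true(loc$extent[["xmin"]] >= cty$extent[["xmin"]] &&
                loc$extent[["xmax"]] <= cty$extent[["xmax"]] &&
                loc$extent[["ymin"]] >= cty$extent[["ymin"]] &&
                loc$extent[["ymax"]] <= cty$extent[["ymax"]])
  expect_identical(level_info("CONTINENTAL")$crs, "EPSG:4326")
  mg <- master_grid("LOCAL", 1000)
  expect_equal(mg$origin_x %% 1000, 0)
  expect_equal(mg$origin_y %% 1000, 0)
})

test_that("align_to_master is the identity on already-aligned layers", {
  mg <- master_grid("LOCAL", 1000)
  g <- grid_spec("EPSG:32632", mg$origin_x + 5000, mg$origin_y - 3000,
                 1000, 6, 6)
  lyr <- seq_layer(g)
  for (m in c("nearest", "bilinear", "block-mean"))
    expect_layers_equal(align_to_master(lyr, mg, m), lyr)
})

test_that("every resampling method preserves constant fields", {
  mg <- master_grid("LOCAL", 1000)
  g <- grid_spec("EPSG:32632", mg$origin_x + 5437, mg$origin_y - 2911,
                 330, 12, 12)
  lyr <- const_layer(3.25, g)
  for (m in c("nearest", "bilinear", "block-mean")) {
    out <- align_to_master(lyr, mg, m)
    expect_true(all(abs(out$values[!is.na(out$values)] - 3.25) < 1e-9))
  }
})

test_that("2:1 block-mean alignment reproduces hand-computed block means", {
  mg <- grid_spec("EPSG:32632", 600000, 5230000, 200, 2, 2)
  g <- grid_spec("EPSG:32632", 600000, 5230000, 100, 4, 4)
  v <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                9, 10, 11, 12,
                13, 14, 15, 16), 4, 4, byrow = TRUE)
  out <- align_to_master(raster_layer(g, v), mg, "block-mean")
  expect_equal(out$values,
               matrix(c(mean(c(1, 2, 5, 6)), mean(c(3, 4, 7, 8)),
                        mean(c(9, 10, 13, 14)), mean(c(11, 12, 15, 16))),
                      2, 2, byrow = TRUE))
})

test_that("aligned origins differ from the master by whole cells", {
  mg <- master_grid("LOCAL", 1000)
  set.seed(11)
  for (i in 1:20) {
    g <- grid_spec("EPSG:32632",
                   mg$origin_x + runif(1, 0, 50000),
                   mg$origin_y - runif(1, 0, 50000),
                   runif(1, 80, 900), sample(3:15, 1), sample(3:15, 1))
    out <- align_to_master(seq_layer(g), mg, "bilinear")
    dx <- (out$grid$origin_x - mg$origin_x) / mg$cell_size
    dy <- (mg$origin_y - out$grid$origin_y) / mg$cell_size
    expect_lt(abs(dx - round(dx)), 1e-9)
    expect_lt(abs(dy - round(dy)), 1e-9)
    # and re-alignment changes nothing
    expect_layers_equal(align_to_master(out, mg, "bilinear"), out)
  }
})

test_that("block_aggregate matches the brute-force block mean", {
  set.seed(3)
  g <- utm_grid(24, 36, 100)
  v <- matrix(rnorm(24 * 36), 24, 36)
  v[sample(length(v), 80)] <- NA
  out <- block_aggregate(raster_layer(g, v), 4)
  brute <- matrix(NA_real_, 6, 9)
  for (i in 1:6) for (j in 1:9) {
    blk <- v[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)]
    if (any(!is.na(blk))) brute[i, j] <- mean(blk, na.rm = TRUE)
  }
  expect_equal(out$values, brute)
  expect_equal(out$grid$cell_size, 400)
})

test_that("block_aggregate handles trivial and partial blocks", {
  lyr <- seq_layer(utm_grid(4, 4, 10))
  expect_layers_equal(block_aggregate(lyr, 1), lyr)
  v <- matrix(c(0.2, 0.4, 0.6, NA), 2, 2)
  out <- block_aggregate(raster_layer(utm_grid(2, 2, 10), v), 2)
  expect_equal(out$values[1, 1], 0.4)
  # non-divisible dimensions are padded with nodata
  out3 <- block_aggregate(seq_layer(utm_grid(3, 3, 10)), 2)
  expect_equal(dim(out3$values), c(2L, 2L))
  expect_equal(out3$values[2, 2], 9)  # single valid cell in padded block
  expect_error(block_aggregate(lyr, 0), "positive")
})

test_that("coordinate transform round-trips and reprojection preserves fields", {
  # known anchor: zone central meridian at the equator maps to the false easting
  eq <- transform_points(9, 0, "EPSG:4326", "EPSG:32632")
  expect_equal(unname(eq[1, "x"]), 500000, tolerance = 1e-6)
  expect_equal(unname(eq[1, "y"]), 0, tolerance = 1e-3)
  pts <- transform_points(c(10.5, 12, 13.5), c(45, 46, 47),
                          "EPSG:4326", "EPSG:32632")
  back <- transform_points(pts[, 1], pts[, 2], "EPSG:32632", "EPSG:4326")
  expect_equal(back[, 1], c(10.5, 12, 13.5), tolerance = 1e-7)
  expect_equal(back[, 2], c(45, 46, 47), tolerance = 1e-7)
  expect_error(transform_points(0, 0, "EPSG:9999", "EPSG:4326"),
               "unsupported CRS")

  g <- utm_grid(20, 20, 500, origin_x = 700000, origin_y = 5100000)
  lyr <- const_layer(7.5, g)
  wgs <- grid_spec("EPSG:4326", 11.56, 46.02, 0.004, 25, 25)
  out <- reproject(lyr, "EPSG:4326", wgs)
  expect_gt(sum(!is.na(out$values)), 100)
  expect_true(all(abs(out$values[!is.na(out$values)] - 7.5) < 1e-9))

  # round trip of a smooth field back onto its own grid
  ctr <- grid_centers(g)
  smooth <- outer(sin(ctr$y / 4000), cos(ctr$x / 4000)) + 2
  src <- raster_layer(g, smooth)
  wide <- grid_spec("EPSG:4326", 11.5, 46.08, 0.002, 120, 150)
  rt <- reproject(reproject(src, "EPSG:4326", wide), "EPSG:32632", g)
  ok <- !is.na(rt$values)
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(rt$values[ok] - smooth[ok])), 0.02)
})

test_that("identity reprojection returns values unchanged", {
  lyr <- seq_layer()
  expect_layers_equal(reproject(lyr, "EPSG:32632", lyr$grid), lyr)
})

test_that("ascii-grid serialization round-trips values, nodata and CRS", {
  dir <- withr::local_tempdir()
  g <- utm_grid(5, 7, 250)
  v <- matrix(as.numeric(sample.int(1000, 35)), 5, 7)
  v[c(3, 17)] <- NA
  lyr <- raster_layer(g, v, "LST", "LOCAL", as.Date("2020-01-12"),
                      "TERRA-DAY")
  path <- file.path(dir, encode_name("LST", "LOCAL", as.Date("2020-01-12"),
                                     "TERRA-DAY", ext = "asc"))
  write_ascii_grid(lyr, path)
  rt <- read_ascii_grid(path)
  expect_identical(rt$values, v)  # integer data round-trip exactly
  expect_true(same_grid(rt$grid, g))
  expect_identical(rt$grid$crs, "EPSG:32632")
  expect_identical(rt$variable, "LST")
  expect_identical(rt$overpass, "TERRA-DAY")
  expect_equal(rt$timestamp, as.Date("2020-01-12"))
  # fractional values round-trip to full double precision
  lyr2 <- raster_layer(g, v / 3)
  p2 <- file.path(dir, "frac.asc")
  write_ascii_grid(lyr2, p2)
  expect_equal(read_ascii_grid(p2)$values, v / 3, tolerance = 1e-12)
})

test_that("cropping keeps georeferencing consistent", {
  lyr <- seq_layer(utm_grid(6, 6, 100))
  e <- grid_extent(lyr$grid)
  sub <- crop_layer(lyr, c(xmin = e[["xmin"]] + 200, xmax = e[["xmin"]] + 400,
                           ymin = e[["ymin"]], ymax = e[["ymax"]] - 100))
  expect_equal(dim(sub$values), c(5L, 2L))
  expect_equal(sub$values, lyr$values[2:6, 3:4])
  expect_error(crop_layer(lyr, c(xmin = 0, xmax = 1, ymin = 0, ymax = 1)),
               "does not intersect")
})
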