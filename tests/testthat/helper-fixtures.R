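# Small in-code fixtures shared across tests.

utm_grid <- function(n_rows = 4, n_cols = 4, cell_size = 100,
                     origin_x = 600000, origin_y = 5230000) {
  grid_spec("EPSG:32632", origin_x, origin_y, cell_size, n_rows, n_cols)
}

const_layer <- function(value, grid = utm_grid(), variable = "LST") {
  raster_layer(grid, value, variable, "LOCAL", as.Date("2020-07-01"))
}

seq_layer <- function(grid = utm_grid(), variable = "LST") {
  raster_layer(grid, matrix(seq_len(grid$n_rows * grid$n_cols),
                            grid$n_rows, grid$n_cols),
               variable, "LOCAL", as.Date("2020-07-01"))
}

# Band set with spatially varying reflectances on a shared grid.
random_bands <- function(seed = 7, n = 8) {
  set.seed(seed)
  g <- utm_grid(n, n, 10)
  lay <- function(lo, hi, var)
    raster_layer(g, matrix(runif(n * n, lo, hi), n, n), var, "LOCAL",
                 as.Date("2020-07-01"))
  band_set(blue = lay(0.02, 0.1, "BLUE"), green = lay(0.05, 0.2, "GREEN"),
           red = lay(0.03, 0.3, "RED"), nir = lay(0.2, 0.6, "NIR"),
           swir = lay(0.05, 0.4, "SWIR"), date = as.Date("2020-07-01"))
}

same_grid <- function(a, b) envgrid:::grids_identical(a, b)

expect_layers_equal <- function(a, b, tolerance = 1e-12) {
  expect_true(same_grid(a$grid, b$grid))
  expect_equal(a$values, b$values, tolerance = tolerance)
}
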