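test_that("percent encoding rounds half-up and round-trips on the percent grid", {
  expect_identical(encode_fraction(c(0, 1)), c(0, 100))
  expect_identical(encode_fraction(2 / 3), 67)
  expect_identical(encode_fraction(0.005), 1)   # half-up, not banker's
  v <- (0:100) / 100
  expect_equal(decode_fraction(encode_fraction(v)), v)
  x <- c(0.123, 0.9949, NA, 0.5)
  expect_true(all(abs(decode_fraction(encode_fraction(x)) - x) <= 0.005,
                  na.rm = TRUE))
  expect_error(encode_fraction(1.2), "outside")
  expect_error(encode_fraction(-0.01), "outside")
  expect_error(decode_fraction(101), "integers")
})

test_that("GeoTIFF round trip preserves values, georeferencing and CRS", {
  g <- make_terrain(fixture_crater())$local
  path <- withr::local_tempfile(fileext = ".tif")
  write_grid(g, path)
  g2 <- read_grid(path, "elevation")
  expect_identical(g2$values, g$values)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$resolution, g$resolution)
  expect_identical(g2$crs_id, g$crs_id)

  # nodata survives the float path
  g$values[3, 7] <- NA
  write_grid(g, path)
  expect_identical(is.na(read_grid(path, "elevation")$values),
                   is.na(g$values))

  # encoded uint8 path with sentinel 255
  enc <- raster_grid(matrix(c(0, 50, NA, 100), 2, 2), 10, c(0, 20),
                     kind = "encoded")
  write_grid(enc, path)
  e2 <- read_grid(path, "encoded")
  expect_identical(e2$values, enc$values)
})

test_that("grid readers enforce the domain invariants", {
  path <- withr::local_tempfile(fileext = ".tif")
  ok <- raster_grid(matrix(c(0, 1, 2, 1), 2, 2), 10, c(0, 20),
                    kind = "forest_mask")
  write_grid(ok, path)
  expect_identical(read_grid(path, "forest_mask")$values, ok$values)

  # a mask with code 3 cannot be constructed nor read back as a mask
  expect_error(raster_grid(matrix(c(0, 1, 2, 3), 2, 2), 10, c(0, 20),
                           kind = "forest_mask"), "codes 0, 1, 2")
  bad <- raster_grid(matrix(c(0, 1, 2, 3), 2, 2), 10, c(0, 20),
                     kind = "elevation")
  write_grid(bad, path)
  expect_error(read_grid(path, "forest_mask"), "kind")

  expect_error(read_grid(tempfile(), "elevation"), "not found")
  expect_error(raster_grid(matrix(1, 2, 2), 10, c(0, 20),
                           crs_id = "EPSG:4326"), "geographic")
  expect_error(raster_grid(matrix(-1, 2, 2), 10, c(0, 20),
                           kind = "canopy_height"), ">= 0")
})

test_that("daily DBT NetCDF files carry 24 encoded steps and round-trip", {
  gm <- raster_grid(matrix(500, 3, 2), 10, c(0, 30), kind = "elevation")
  arr <- array(runif(24 * 3 * 2), c(24, 3, 2))
  arr[, 2, 1] <- NA
  path <- withr::local_tempfile(fileext = ".nc")
  write_dbt_netcdf(arr, "2020-03-01", gm, path)
  rt <- read_dbt_netcdf(path)
  expect_identical(rt$dbt, decode_fraction(encode_fraction(arr)))
  expect_identical(rt$time[1],
                   as.POSIXct("2020-03-01 00:00:00", tz = "Etc/GMT-1"))
  expect_equal(as.numeric(diff(rt$time), units = "hours"), rep(1, 23))
  expect_equal(rt$x, c(5, 15))
  expect_equal(rt$y, c(25, 15, 5))
  expect_identical(rt$crs_id, gm$crs_id)

  expect_error(write_dbt_netcdf(arr[1:23, , , drop = FALSE], "2020-03-01",
                                gm, path), "24 hourly")

  # all-zero day decodes to exactly zero
  write_dbt_netcdf(array(0, c(24, 3, 2)), "2020-03-02", gm, path)
  expect_true(all(read_dbt_netcdf(path)$dbt == 0))
})

test_that("a year of daily files covers 8784 hourly steps in 366 files", {
  days <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  expect_length(days, 366)
  gm <- raster_grid(matrix(500, 1, 1), 10, c(0, 10), kind = "elevation")
  dir <- withr::local_tempdir()
  # write the two leap-relevant edge days plus a sample; shape is identical
  # for every file, the full enumeration is over timestamps
  for (i in c(1, 60, 366)) {
    d <- days[i]                       # for-loops strip the Date class
    write_dbt_netcdf(array(0.5, c(24, 1, 1)), d, gm,
                     file.path(dir, paste0(format(d, "%Y%m%d"), ".nc")))
  }
  steps <- length(days) * 24L
  expect_identical(steps, 8784L)
  got <- sum(vapply(list.files(dir, full.names = TRUE), function(f)
    length(read_dbt_netcdf(f)$time), integer(1)))
  expect_identical(got, 72L)
})
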