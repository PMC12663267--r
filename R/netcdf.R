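## Daily NetCDF output for hourly direct-beam transmissivity.
##
## One file per calendar day and canopy layer, with dimensions (time, y, x),
## 24 hourly steps, 8-bit percentage encoding (nodata 255) and a CF-style
## time coordinate in hours since local midnight at a fixed UTC+1 offset.
## Each timestamp marks the *start* of its averaging period.

#' Write one day of hourly DBT values to a NetCDF file
#'
#' @param dbt Numeric array `[24, ny, nx]` of DBT fractions in `[0, 1]`
#'   (`NA` = nodata), hour `h` in `[h-1, h)` local time. A `[24]` vector is
#'   accepted for a single-point grid.
#' @param day A `Date` (or string) giving the calendar day.
#' @param grid A `hemirad_grid` providing the georeferencing of the x/y
#'   coordinates (cell centres).
#' @param path Output file path.
#' @param variable Variable name in the file, by default `"DBT"`.
#' @return `path`, invisibly.
#' @export
write_dbt_netcdf <- function(dbt, day, grid, path, variable = "DBT") {
  day <- as.Date(day)
  if (is.null(dim(dbt))) dbt <- array(dbt, dim = c(length(dbt), 1, 1))
  if (length(dim(dbt)) != 3 || dim(dbt)[1] != 24)
    stop("dbt must have 24 hourly steps for ", format(day),
         " (got ", dim(dbt)[1], ")")
  d <- dim(grid$values)
  if (dim(dbt)[2] != d[1] || dim(dbt)[3] != d[2])
    stop("dbt spatial dimensions do not match the grid")
  enc <- encode_fraction(dbt)
  enc[is.na(enc)] <- 255

  ny <- d[1]; nx <- d[2]
  xs <- grid$origin[1] + (seq_len(nx) - 0.5) * grid$resolution
  ys <- grid$origin[2] - (seq_len(ny) - 0.5) * grid$resolution
  tunits <- sprintf("hours since %s 00:00:00 +01:00", format(day))
  dim_t <- ncdf4::ncdim_def("time", tunits, vals = 0:23,
                            longname = "start of hourly averaging period")
  dim_y <- ncdf4::ncdim_def("y", "m", vals = ys)
  dim_x <- ncdf4::ncdim_def("x", "m", vals = xs)
  var <- ncdf4::ncvar_def(variable, "percent", list(dim_x, dim_y, dim_t),
                          missval = NULL, prec = "byte",
                          longname = "direct-beam transmissivity, percent")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ## 8-bit storage: nodata 255 is -1 in the signed NC_BYTE on disk, flagged
  ## with the _Unsigned convention. Array comes in as [time, y, x]; ncdf4
  ## wants [x, y, time].
  store <- ifelse(enc > 127, enc - 256, enc)
  ncdf4::ncvar_put(nc, var, aperm(store, c(3, 2, 1)))
  ncdf4::ncatt_put(nc, var, "_Unsigned", "true")
  ncdf4::ncatt_put(nc, var, "note",
                   "values are 8-bit percentages 0-100; divide by 100; 255 = nodata")
  ncdf4::ncatt_put(nc, 0, "crs_id", grid$crs_id)
  ncdf4::ncatt_put(nc, 0, "timezone", "CET (fixed UTC+1)")
  invisible(path)
}

#' Read a daily DBT NetCDF file back as fractions
#'
#' @param path Path written by [write_dbt_netcdf()].
#' @param variable Variable name, by default `"DBT"`.
#' @return A list with `dbt` (`[24, ny, nx]` array of fractions, `NA` =
#'   nodata), `time` (POSIXct, UTC+1, start of each averaging period), `x`,
#'   `y` (cell-centre coordinates) and `crs_id`.
#' @export
read_dbt_netcdf <- function(path, variable = "DBT") {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  raw <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  tunits <- ncdf4::ncatt_get(nc, "time", "units")$value
  day <- sub("^hours since ([0-9-]+).*$", "\\1", tunits)
  hours <- ncdf4::ncvar_get(nc, "time")
  t0 <- as.POSIXct(paste(day, "00:00:00"), tz = "Etc/GMT-1")
  arr <- aperm(raw, c(3, 2, 1))      # back to [time, y, x]
  arr[arr < 0] <- arr[arr < 0] + 256 # undo signed-byte storage
  arr[arr == 255] <- NA
  list(dbt = decode_fraction(arr),
       time = t0 + hours * 3600,
       x = as.vector(ncdf4::ncvar_get(nc, "x")),
       y = as.vector(ncdf4::ncvar_get(nc, "y")),
       crs_id = ncdf4::ncatt_get(nc, 0, "crs_id")$value)
}
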