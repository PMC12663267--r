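## Solar geometry (NOAA parameterisation) and direct-beam transmissivity.

RAD <- pi / 180

## Core NOAA solar-calculator equation set, vectorised over Julian day (UT).
noaa_core <- function(jd_ut) {
  jc <- (jd_ut - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(gmas * RAD) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * RAD) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * RAD) * 0.000289
  truelong <- gmls + eqctr
  omega <- 125.04 - 1934.136 * jc
  applong <- truelong - 0.00569 - 0.00478 * sin(omega * RAD)
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(omega * RAD)
  decl <- asin(sin(obliq * RAD) * sin(applong * RAD)) / RAD
  vary <- tan(obliq / 2 * RAD)^2
  eqtime <- 4 / RAD * (vary * sin(2 * gmls * RAD) -
    2 * ecc * sin(gmas * RAD) +
    4 * ecc * vary * sin(gmas * RAD) * cos(2 * gmls * RAD) -
    0.5 * vary^2 * sin(4 * gmls * RAD) -
    1.25 * ecc^2 * sin(2 * gmas * RAD))
  list(decl = decl, eqtime = eqtime)
}

#' Solar position from the NOAA parameterisation
#'
#' Computes solar zenith and azimuth for civil timestamps at a geographic
#' point, from the NOAA solar-calculator equation set (Julian century,
#' geometric mean longitude/anomaly, equation of time, declination, hour
#' angle). Zenith angles above 90 degrees mean the sun is below the
#' astronomical horizon. No atmospheric refraction is applied unless
#' `refraction = TRUE`.
#'
#' @param time A `POSIXct` vector (any timezone; converted internally).
#' @param latitude,longitude Geographic coordinates in degrees (east/north
#'   positive).
#' @param refraction Logical; apply the NOAA refraction correction to the
#'   solar elevation.
#' @return A data frame with columns `time`, `zenith`, `azimuth` (degrees,
#'   azimuth clockwise from north in `[0, 360)`).
#' @examples
#' noon <- as.POSIXct("2020-06-21 12:28:00", tz = "Etc/GMT-1")
#' solar_position(noon, 46.5, 8.0)
#' @export
solar_position <- function(time, latitude, longitude, refraction = FALSE) {
  stopifnot(inherits(time, "POSIXct"))
  jd <- as.numeric(time) / 86400 + 2440587.5   # UT Julian day
  nc <- noaa_core(jd)
  ut_min <- ((jd + 0.5) %% 1) * 1440
  tst <- (ut_min + nc$eqtime + 4 * longitude) %% 1440
  ha <- tst / 4 - 180
  lat <- latitude * RAD
  decl <- nc$decl * RAD
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha * RAD)
  cosz <- pmin(1, pmax(-1, cosz))
  zen <- acos(cosz) / RAD
  sinz <- sin(zen * RAD)
  cosaz <- (sin(lat) * cosz - sin(decl)) / (cos(lat) * sinz)
  cosaz[sinz < 1e-12] <- 1
  cosaz <- pmin(1, pmax(-1, cosaz))
  az <- ifelse(ha > 0,
               (acos(cosaz) / RAD + 180) %% 360,
               (540 - acos(cosaz) / RAD) %% 360)
  if (refraction) {
    elev <- 90 - zen
    re <- numeric(length(elev))
    hi <- elev > 85
    mid <- elev > 5 & !hi
    lo <- elev > -0.575 & !hi & !mid
    te <- tan(elev * RAD)
    re[mid] <- (58.1 / te[mid] - 0.07 / te[mid]^3 +
                  0.000086 / te[mid]^5) / 3600
    e <- elev[lo]
    re[lo] <- (1735 + e * (-518.2 + e * (103.4 + e * (-12.79 +
      e * 0.711)))) / 3600
    re[!hi & !mid & !lo] <- (-20.772 / te[!hi & !mid & !lo]) / 3600
    zen <- zen - re
  }
  data.frame(time = time, zenith = zen, azimuth = az)
}

#' Annual solar track at a point
#'
#' Solar positions at a fixed cadence from 1 January 00:00 to 31 December
#' 24:00 minus one step, in fixed-offset CET (UTC+1). Leap years are
#' covered; 2020 yields `366 * 24 * 60 / step` positions.
#'
#' @param year Calendar year.
#' @param latitude,longitude Geographic coordinates in degrees.
#' @param step Cadence in minutes; must divide 60.
#' @param refraction Passed to [solar_position()].
#' @return A data frame `time`, `zenith`, `azimuth`.
#' @export
solar_track <- function(year, latitude, longitude, step = 2,
                        refraction = FALSE) {
  if (60 %% step != 0) stop("step must divide 60")
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "Etc/GMT-1")
  t1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year + 1), tz = "Etc/GMT-1")
  n <- as.numeric(difftime(t1, t0, units = "mins")) / step
  times <- t0 + (seq_len(n) - 1) * step * 60
  solar_position(times, latitude, longitude, refraction)
}

## Sample-offset grid covering the solar disc: (dx, dy) in degrees on a
## local tangent plane, dy along zenith. The 0.53-degree disc is smaller
## than one 1-degree image cell, so supersampling recovers partial
## occlusion (the disc overlaps 1-4 cells).
disc_offsets <- function(config) {
  r <- config$solar_disc_diameter / 2
  n <- config$disc_grid
  u <- seq(-r, r, length.out = n)
  g <- expand.grid(dx = u, dy = u)
  g[g$dx^2 + g$dy^2 <= r^2 + 1e-12, , drop = FALSE]
}

#' Direct-beam transmissivity at given solar positions
#'
#' Samples the hemispheric image over the solar disc (angular diameter
#' `config$solar_disc_diameter`, supersampled on a fixed offset grid) and
#' returns the fraction of disc samples that see sky. Disc samples falling
#' at zenith >= 90 are outside the image and are excluded from the average,
#' so an unobstructed scene gives exactly 1 whenever the sun centre is above
#' the astronomical horizon; positions with solar zenith >= 90 return 0.
#'
#' @param image A `hemi_image`.
#' @param zenith,azimuth Solar position vectors in degrees (e.g. columns of
#'   [solar_track()]), or a data frame with those columns passed as
#'   `zenith`.
#' @param config A [model_config()].
#' @return A numeric vector of DBT fractions in `[0, 1]`.
#' @export
dbt_at_position <- function(image, zenith, azimuth = NULL,
                            config = model_config()) {
  if (is.data.frame(zenith)) {
    azimuth <- zenith$azimuth
    zenith <- zenith$zenith
  }
  stopifnot(length(zenith) == length(azimuth))
  zs <- attr(image, "zenith_step"); as_ <- attr(image, "azimuth_step")
  m <- unclass(image)
  offs <- disc_offsets(config)
  out <- numeric(length(zenith))
  day <- which(zenith < 90)
  if (!length(day)) return(out)
  chunk <- 20000L
  for (i0 in seq(1, length(day), by = chunk)) {
    idx <- day[i0:min(i0 + chunk - 1L, length(day))]
    zen <- zenith[idx]; az <- azimuth[idx]
    ## azimuthal offsets scale with 1/sin(zenith); clamp near the pole where
    ## the disc covers all azimuths of a tiny-solid-angle cell anyway
    sc <- 1 / pmax(sin(zen * RAD), sin(1 * RAD))
    zsamp <- outer(zen, offs$dy, "+")
    asamp <- outer(az, numeric(nrow(offs)), "+") + outer(sc, offs$dx, "*")
    neg <- zsamp < 0
    if (any(neg)) {
      asamp[neg] <- asamp[neg] + 180
      zsamp[neg] <- -zsamp[neg]
    }
    valid <- zsamp < 90
    zi <- pmin(floor(zsamp / zs) + 1, nrow(m))
    ai <- floor((asamp %% 360) / as_) + 1
    ai[ai > ncol(m)] <- 1L
    sky <- matrix(FALSE, nrow(zsamp), ncol(zsamp))
    sky[valid] <- m[cbind(zi[valid], ai[valid])]
    out[idx] <- rowSums(sky) / pmax(rowSums(valid), 1)
  }
  out
}

#' Hourly DBT series for a hemispheric image
#'
#' Runs the solar track at the configured cadence (default 2 minutes),
#' evaluates DBT at every position, and averages to hourly resolution. Hour
#' `H` is the arithmetic mean of all fine values in `[H:00, H+1:00)` and is
#' timestamped `H:00` (start of the averaging period, fixed UTC+1).
#'
#' @param image A `hemi_image`.
#' @param latitude,longitude Geographic coordinates of the point (degrees).
#' @param config A [model_config()] (year, cadence, disc geometry).
#' @param days Optional `Date` vector restricting the track to given days.
#' @return A data frame `time`, `dbt` at hourly cadence (8784 rows for a
#'   full 2020 run), with attribute `cadence = 60`.
#' @export
dbt_track <- function(image, latitude, longitude, config = model_config(),
                      days = NULL) {
  step <- config$track_step
  if (is.null(days)) {
    track <- solar_track(config$year, latitude, longitude, step,
                         config$refraction)
  } else {
    days <- as.Date(days)
    per <- 24 * 60 / step
    times <- do.call(c, lapply(days, function(d) {
      t0 <- as.POSIXct(paste(format(d), "00:00:00"), tz = "Etc/GMT-1")
      t0 + (seq_len(per) - 1) * step * 60
    }))
    track <- solar_position(times, latitude, longitude, config$refraction)
  }
  fine <- dbt_at_position(image, track$zenith, track$azimuth, config)
  hourly_average(data.frame(time = track$time, dbt = fine))
}

#' Average a fine-cadence DBT series to hourly resolution
#'
#' @param series A data frame with `time` (POSIXct, aligned to hour
#'   boundaries, regular cadence dividing 60 minutes) and `dbt`.
#' @return A data frame `time`, `dbt` with one row per complete hour; the
#'   timestamp is the start of the averaging period.
#' @export
hourly_average <- function(series) {
  stopifnot(is.data.frame(series), all(c("time", "dbt") %in% names(series)))
  tt <- series$time
  n <- length(tt)
  if (n == 0) stop("empty series")
  cad <- if (n > 1) as.numeric(difftime(tt[2], tt[1], units = "mins")) else 60
  if (cad <= 0 || 60 %% cad != 0)
    stop("series cadence must divide 60 minutes")
  per <- as.integer(60 / cad)
  if (n %% per != 0) stop("series does not cover complete hours")
  if (as.numeric(tt[1]) %% 3600 != 0)
    stop("series must start on an hour boundary")
  if (n > 1 && any(abs(diff(as.numeric(tt)) - cad * 60) > 1e-6))
    stop("series cadence is irregular")
  hourly <- colMeans(matrix(series$dbt, nrow = per))
  out <- data.frame(time = tt[seq(1, n, by = per)], dbt = hourly)
  attr(out, "cadence") <- 60
  out
}
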