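# Independent scalar implementation of the NOAA solar-calculator equations,
# written from the published spreadsheet row by row: calendar-component
# Julian day, local-clock true solar time. Used only as an oracle against
# the package's vectorised UT-based implementation.

oracle_solar_position <- function(year, month, day, hour, minute, sec,
                                  tz, lat, lon) {
  deg2rad <- function(d) d * pi / 180
  rad2deg <- function(r) r * 180 / pi

  # Julian day from calendar components (Gregorian)
  y <- year; m <- month
  if (m <= 2) { y <- y - 1; m <- m + 12 }
  A <- floor(y / 100); B <- 2 - A + floor(A / 4)
  jd <- floor(365.25 * (y + 4716)) + floor(30.6001 * (m + 1)) + day +
    B - 1524.5 + (hour + minute / 60 + sec / 3600 - tz) / 24

  jc <- (jd - 2451545) / 36525
  gml <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(deg2rad(gma)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * gma)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * gma)) * 0.000289
  stl <- gml + seqc
  sal <- stl - 0.00569 - 0.00478 * sin(deg2rad(125.04 - 1934.136 * jc))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc *
    0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(deg2rad(125.04 - 1934.136 * jc))
  decl <- rad2deg(asin(sin(deg2rad(oc)) * sin(deg2rad(sal))))
  vy <- tan(deg2rad(oc / 2))^2
  eqtime <- 4 * rad2deg(vy * sin(2 * deg2rad(gml)) -
    2 * eeo * sin(deg2rad(gma)) +
    4 * eeo * vy * sin(deg2rad(gma)) * cos(2 * deg2rad(gml)) -
    0.5 * vy * vy * sin(4 * deg2rad(gml)) -
    1.25 * eeo * eeo * sin(2 * deg2rad(gma)))

  clock_min <- hour * 60 + minute + sec / 60
  tst <- (clock_min + eqtime + 4 * lon - 60 * tz) %% 1440
  ha <- if (tst / 4 < 0) tst / 4 + 180 else tst / 4 - 180

  cosz <- sin(deg2rad(lat)) * sin(deg2rad(decl)) +
    cos(deg2rad(lat)) * cos(deg2rad(decl)) * cos(deg2rad(ha))
  cosz <- min(1, max(-1, cosz))
  zen <- rad2deg(acos(cosz))
  caz <- (sin(deg2rad(lat)) * cosz - sin(deg2rad(decl))) /
    (cos(deg2rad(lat)) * sin(deg2rad(zen)))
  caz <- min(1, max(-1, caz))
  az <- if (ha > 0) (rad2deg(acos(caz)) + 180) %% 360
        else (540 - rad2deg(acos(caz))) %% 360
  list(zenith = zen, azimuth = az)
}
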