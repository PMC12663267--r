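test_that("solar position matches an independent NOAA implementation", {
  ## compare across the year, the day, and several sites
  times <- as.POSIXct("2020-01-01 00:07:00", tz = "Etc/GMT-1") +
    round(seq(0, 365 * 86400, length.out = 60))
  sites <- list(c(46.5, 8.0), c(47.2, 9.5), c(45.9, 6.1))
  for (s in sites) {
    got <- solar_position(times, s[1], s[2])
    lt <- as.POSIXlt(times)
    for (i in seq_along(times)) {
      o <- oracle_solar_position(lt$year[i] + 1900, lt$mon[i] + 1,
                                 lt$mday[i], lt$hour[i], lt$min[i],
                                 lt$sec[i], tz = 1, s[1], s[2])
      expect_lt(abs(got$zenith[i] - o$zenith), 0.01)
      daz <- abs(got$azimuth[i] - o$azimuth) %% 360
      expect_lt(min(daz, 360 - daz), 0.01)
    }
  }
})

test_that("solar geometry honours the classical identities", {
  lat <- 46.5; lon <- 8.0
  ## equinox: at solar noon the zenith angle equals the latitude (decl ~ 0)
  noon_track <- solar_position(as.POSIXct("2020-03-20 00:00", tz = "Etc/GMT-1") +
                                 seq(0, 86340, by = 60), lat, lon)
  imin <- which.min(noon_track$zenith)
  expect_lt(abs(noon_track$zenith[imin] - lat), 0.5)
  ## meridian crossing: azimuth ~ 180 at solar noon
  expect_lt(abs(noon_track$azimuth[imin] - 180), 1)
  ## midwinter solar midnight: sun far below the horizon
  mid <- solar_position(as.POSIXct("2020-12-21 00:30", tz = "Etc/GMT-1"),
                        lat, lon)
  expect_gt(mid$zenith, 90)
})

test_that("the annual track has the advertised cadence and continuity", {
  tr60 <- solar_track(2020, 46.5, 8, step = 60)
  expect_identical(nrow(tr60), 8784L)
  expect_identical(format(tr60$time[1], "%Y-%m-%d %H:%M"), "2020-01-01 00:00")
  expect_identical(format(tr60$time[8784], "%Y-%m-%d %H:%M"),
                   "2020-12-31 23:00")
  tr2 <- solar_track(2020, 46.5, 8, step = 2)
  expect_identical(nrow(tr2), 263520L)
  ## smoothness of the ephemeris at 2-minute cadence
  expect_lt(max(abs(diff(tr2$zenith[1:2000]))), 1)
  ## non-leap year
  expect_identical(nrow(solar_track(2021, 46.5, 8, step = 60)), 8760L)
  expect_error(solar_track(2020, 46.5, 8, step = 7), "divide")
})

test_that("DBT disc sampling handles open sky, occlusion and bisection", {
  cfg <- model_config()
  open <- all_sky_image()
  expect_identical(dbt_at_position(open, 45, 180, cfg), 1)
  expect_identical(dbt_at_position(open, 95, 180, cfg), 0)
  ## terrain horizon at 40 deg elevation; sun 5 deg below it -> 0
  img <- horizon_to_image(horizon_profile(rep(40, 360)), cfg)
  expect_identical(dbt_at_position(img, 90 - 35, 180, cfg), 0)
  ## sun well above -> 1
  expect_identical(dbt_at_position(img, 90 - 60, 180, cfg), 1)
  ## horizon exactly bisecting the disc -> about one half
  half <- dbt_at_position(img, 90 - 40, 180, cfg)
  expect_lt(abs(half - 0.5), 0.15)
  ## vectorised call agrees with scalar calls
  zs <- c(20, 49.7, 50.3, 95)
  vec <- dbt_at_position(img, zs, rep(180, 4), cfg)
  ind <- vapply(zs, function(z) dbt_at_position(img, z, 180, cfg),
                numeric(1))
  expect_identical(vec, ind)
})

test_that("the flat-scene DBT is a step function at the astronomical horizon", {
  cfg <- model_config()
  open <- all_sky_image()
  day <- as.POSIXct("2020-06-21 00:00", tz = "Etc/GMT-1") +
    seq(0, 86399, by = 120)
  tr <- solar_position(day, 46.5, 8)
  d <- dbt_at_position(open, tr$zenith, tr$azimuth, cfg)
  expect_identical(d, as.numeric(tr$zenith < 90))
})

test_that("hourly averaging is exact and mean-preserving", {
  t0 <- as.POSIXct("2020-06-21 00:00", tz = "Etc/GMT-1")
  tt <- t0 + seq(0, 3 * 3600 - 1, by = 120)
  const <- data.frame(time = tt, dbt = rep(0.37, length(tt)))
  hc <- hourly_average(const)
  expect_equal(hc$dbt, rep(0.37, 3))
  expect_identical(hc$time, t0 + (0:2) * 3600)
  ## 1 for the first 30 minutes of each hour, 0 after -> 0.5
  halves <- data.frame(time = tt,
                       dbt = rep(c(rep(1, 15), rep(0, 15)), 3))
  expect_equal(hourly_average(halves)$dbt, rep(0.5, 3))
  ## mean preservation on an arbitrary series
  set.seed(4)
  rnd <- data.frame(time = tt, dbt = runif(length(tt)))
  expect_equal(mean(hourly_average(rnd)$dbt), mean(rnd$dbt))
  ## misalignment errors
  shifted <- transform(rnd, time = time + 120)
  expect_error(hourly_average(shifted), "hour boundary")
  expect_error(hourly_average(rnd[1:50, ]), "complete hours")
})

test_that("dbt_track produces hourly values bounded by daylight", {
  cfg <- model_config()
  img <- horizon_to_image(horizon_profile(rep(20, 360)), cfg)
  s <- dbt_track(img, 46.5, 8, cfg, days = as.Date("2020-03-15"))
  expect_identical(nrow(s), 24L)
  expect_true(all(s$dbt >= 0 & s$dbt <= 1))
  expect_true(all(s$dbt[c(1:5, 22:24)] == 0))   # night hours
  expect_gt(max(s$dbt), 0.9)                    # midday sun above 20 deg
})
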