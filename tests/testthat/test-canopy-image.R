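test_that("no canopy gives zero path everywhere and a terrain canopy-top", {
  cfg <- model_config()
  spec <- scene_spec("flat", "none", extent = 64, local_res = 1)
  terr <- make_terrain(spec)
  chm <- make_forest(spec)$chm
  lam <- uniform_lambda(chm, 0.5)
  f <- canopy_horizon_and_thickness(chm, terr$local, c(32, 32), lam, cfg)
  expect_true(all(f$l == 0))
  expect_true(all(f$laml == 0))
  th <- horizon_from_grid(terr$local, c(32, 32), cfg$max_canopy_range)
  expect_equal(as.numeric(f$canopy_top), as.numeric(th), tolerance = 1e-9)
})

test_that("a cuboid crown yields the analytic ray-box path length", {
  cfg <- model_config()
  ## 2 m wide, 10 m tall crown centred 5 m north of the viewer: the
  ## near-horizontal due-north ray crosses the full 2 m of crown
  spec <- scene_spec("flat", "single_crown", extent = 60, crown_size = 2,
                     crown_height = 10, crown_offset = c(0, 5),
                     local_res = 1, chm_res = 1)
  terr <- make_terrain(spec)
  chm <- make_forest(spec)$chm
  lam <- uniform_lambda(chm, 0.5)
  f <- canopy_horizon_and_thickness(chm, terr$local, c(30, 30), lam, cfg)
  expect_equal(f$l[90, 1], 2, tolerance = sqrt(2) * cfg$canopy_ray_step)
  ## path-weighted lambda is lambda * l for uniform lambda
  expect_equal(f$laml[90, 1], 0.5 * f$l[90, 1], tolerance = 1e-9)
  ## a due-south ray sees nothing
  expect_equal(f$l[90, 181], 0)
})

test_that("a vertical ray through a uniform slab accumulates the slab height", {
  cfg <- model_config()
  spec <- fixture_slab(20)
  terr <- make_terrain(spec)
  chm <- make_forest(spec)$chm
  lam <- uniform_lambda(chm, 0.3)
  f <- canopy_horizon_and_thickness(chm, terr$local, c(32, 32), lam, cfg)
  expect_equal(f$l[1, 1], 20, tolerance = sqrt(3) * chm$resolution)
  expect_equal(f$laml[1, 1], 0.3 * f$l[1, 1], tolerance = 1e-9)
})

test_that("uniform-lambda accumulation matches lambda * total path length", {
  cfg <- model_config()
  spec <- fixture_gapped()
  terr <- make_terrain(spec)
  chm <- make_forest(spec)$chm
  f <- canopy_horizon_and_thickness(chm, terr$local, c(50, 50),
                                    uniform_lambda(chm, 0.42), cfg)
  expect_equal(f$laml, 0.42 * f$l, tolerance = 1e-9)
  expect_true(all(f$l >= 0))
})

test_that("transmission follows the exponential path-length law", {
  cfg <- model_config()  # G = 0.5
  mk <- function(laml) structure(list(l = laml, laml = laml),
                                 class = "path_length_field")
  z <- matrix(0, 90, 360)
  expect_true(all(transmission_probability(mk(z), cfg) == 1))
  one <- matrix(1, 90, 360)   # lambda*l = 1 -> p = exp(-0.5)
  expect_equal(transmission_probability(mk(one), cfg)[5, 5], exp(-0.5),
               tolerance = 1e-12)
  ## log-linearity: doubling the path doubles -log p
  p1 <- transmission_probability(mk(one), cfg)
  p2 <- transmission_probability(mk(2 * one), cfg)
  expect_equal(log(p2), 2 * log(p1), tolerance = 1e-12)
  ## adding canopy anywhere never increases transmission
  more <- one; more[10, 10] <- 3
  expect_true(all(transmission_probability(mk(more), cfg) <= p1))
  expect_error(transmission_probability(mk(-one), cfg), "negative")
})

test_that("binarisation is calibrated, seeded and reproducible", {
  expect_true(all(binarise_probability(uniform_field_p(1), 1)))
  expect_false(any(binarise_probability(uniform_field_p(0), 1)))
  p <- uniform_field_p(0.6)
  img <- binarise_probability(p, rng_seed = 7)
  sd3 <- 3 * sqrt(0.6 * 0.4 / (90 * 360))
  expect_lt(abs(mean(img) - 0.6), sd3 * 2)   # single-seed sanity bound
  expect_identical(unclass(binarise_probability(p, rng_seed = 7)),
                   unclass(img))
  expect_false(identical(unclass(binarise_probability(p, rng_seed = 8)),
                         unclass(img)))
  ## threshold mode is deterministic
  thr <- binarise_probability(uniform_field_p(0.49), mode = "threshold")
  expect_false(any(thr))
  thr2 <- binarise_probability(uniform_field_p(0.51), mode = "threshold")
  expect_true(all(thr2))
  ## shared uniforms preserve nesting between two probability fields
  u <- matrix(runif(90 * 360), 90, 360)
  lo <- binarise_probability(uniform_field_p(0.3), uniforms = u)
  hi <- binarise_probability(uniform_field_p(0.7), uniforms = u)
  expect_true(all(hi[lo]))   # every sky direction at p=0.3 is sky at p=0.7
})

test_that("binarisation leaves the caller's RNG stream untouched", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(binarise_probability(uniform_field_p(0.5), rng_seed = 99))
  expect_identical(runif(1), a)
})

test_that("image composition is the intersection of sky", {
  terr <- horizon_to_image(horizon_profile(rep(20, 360)))
  all_sky <- all_sky_image()
  expect_identical(unclass(compose_images(terr, all_sky)), unclass(terr))
  none <- hemi_image(matrix(FALSE, 90, 360))
  expect_false(any(compose_images(none, all_sky)))
  set.seed(5)
  a <- hemi_image(matrix(runif(90 * 360) < 0.7, 90, 360))
  b <- hemi_image(matrix(runif(90 * 360) < 0.5, 90, 360))
  comp <- compose_images(a, b)
  expect_lte(mean(comp), min(mean(a), mean(b)))
  expect_identical(as.logical(comp), as.logical(unclass(a) & unclass(b)))
  expect_error(compose_images(a, hemi_image(matrix(TRUE, 45, 360),
                                            zenith_step = 2)),
               "different angular")
})

test_that("with lambda -> 0 the composed image converges to terrain-only", {
  cfg <- model_config()
  spec <- fixture_gapped()
  terr <- make_terrain(spec)
  chm <- make_forest(spec)$chm
  pt <- c(50, 50)
  timg <- horizon_to_image(horizon_from_grid(terr$local, pt,
                                             cfg$local_radius), cfg)
  f <- canopy_horizon_and_thickness(chm, terr$local, pt,
                                    uniform_lambda(chm, 1e-9), cfg)
  p <- transmission_probability(f, cfg)
  canopy <- binarise_probability(p, rng_seed = 1)
  expect_identical(unclass(compose_images(timg, canopy)), unclass(timg))
})
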