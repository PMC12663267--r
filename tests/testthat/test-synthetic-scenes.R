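test_that("scene generation is bitwise reproducible from the spec", {
  spec <- fixture_gapped(seed = 5)
  a <- make_terrain(spec); b <- make_terrain(spec)
  expect_identical(a$local$values, b$local$values)
  fa <- make_forest(spec); fb <- make_forest(spec)
  expect_identical(fa$chm$values, fb$chm$values)
  expect_identical(fa$mask$values, fb$mask$values)
  ## a different seed moves the crowns
  fc <- make_forest(fixture_gapped(seed = 6))
  expect_false(identical(fa$chm$values, fc$chm$values))
})

test_that("flat scenes are constant at both resolutions", {
  terr <- make_terrain(scene_spec("flat", "none", extent = 200, z0 = 500))
  expect_true(all(terr$local$values == 500))
  expect_true(all(terr$regional$values == 500))
  expect_identical(dim(terr$local$values), c(40L, 40L))
  expect_identical(dim(terr$regional$values), c(4L, 4L))
})

test_that("the crater rim subtends the requested angle from the centre", {
  spec <- fixture_crater()
  ctr <- c(spec$extent / 2, spec$extent / 2)
  oracle <- oracle_horizon(spec, ctr, radius = 150, step = 0.1)
  ## one 0.1 m march step at the 80 m rim subtends ~0.04 degrees
  expect_true(all(abs(oracle - spec$rim_angle) < 0.05))
  h <- horizon_from_grid(make_terrain(spec)$local, ctr, 150)
  subtense <- atan(spec$local_res / spec$rim_radius) * 180 / pi
  expect_true(all(abs(as.numeric(h) - spec$rim_angle) <= subtense))
})

test_that("an inclined plane yields the closed-form sinusoidal horizon", {
  slope <- 12; aspect <- 90     # dips towards east
  spec <- fixture_slope(slope, aspect)
  ctr <- c(spec$extent / 2, spec$extent / 2)
  h <- horizon_from_grid(make_terrain(spec)$local, ctr, 140)
  az <- attr(h, "azimuth")
  ## along-ray gradient: uphill (west) rises at `slope`, downhill negative
  closed <- atan(-tan(slope * pi / 180) * cos((az - aspect) * pi / 180)) *
    180 / pi
  subtense <- atan(spec$local_res / 20) * 180 / pi  # near-field cell
  expect_lt(max(abs(as.numeric(h) - closed)), subtense)
  expect_equal(max(h), slope, tolerance = 0.5)
  expect_equal(az[which.max(h)], (aspect + 180) %% 360, tolerance = 1)
})

test_that("forest layouts follow their specification", {
  ## none: empty canopy, all open
  f0 <- make_forest(scene_spec("flat", "none", extent = 100))
  expect_true(all(f0$chm$values == 0))
  expect_true(all(f0$mask$values == 2))

  ## single crown: footprint height, mask 1 within the 25 m buffer
  sp1 <- scene_spec("flat", "single_crown", extent = 100, crown_size = 10,
                    crown_height = 15, crown_offset = c(0, 0))
  f1 <- make_forest(sp1)
  expect_equal(max(f1$chm$values), 15)
  expect_equal(sum(f1$chm$values > 0), 100)   # 10 m x 10 m of 1 m cells
  ## mask cell centres within buffer of the footprint are forest
  ctr_cell <- f1$mask$values[5, 5]            # centre cell (45,55)
  expect_identical(ctr_cell, 1)
  expect_identical(f1$mask$values[1, 1], 2)   # corner: ~57 m away

  ## plantation: floor(extent/spacing)^2 crowns
  sp2 <- scene_spec("flat", "plantation", extent = 60, spacing = 10,
                    crown_size = 4, crown_height = 10)
  cr <- hemirad:::scene_crowns(sp2)
  expect_identical(nrow(cr), 36L)

  ## gapped: no crown centre inside the gap radius
  sp3 <- fixture_gapped()
  cr3 <- hemirad:::scene_crowns(sp3)
  expect_identical(nrow(cr3), as.integer(sp3$n_crowns))
  d <- sqrt((cr3$x - 50)^2 + (cr3$y - 50)^2)
  expect_true(all(d > sp3$gap_radius))
})

test_that("the visibility oracle resolves free, blocked and canopy paths", {
  flat <- scene_spec("flat", "none", extent = 100)
  o <- oracle_visibility(flat, c(50, 50), 45, 123)
  expect_true(o$free)
  expect_identical(o$canopy_path_length, 0)

  crater <- fixture_crater()
  ctr <- c(crater$extent / 2, crater$extent / 2)
  blocked <- oracle_visibility(crater, ctr, 90 - 20, 45)   # 20 deg < 30 rim
  expect_true(blocked$terrain_blocked)
  clear <- oracle_visibility(crater, ctr, 90 - 40, 45)
  expect_true(clear$free)

  slab <- fixture_slab(20)
  vert <- oracle_visibility(slab, c(32, 32), 0, 0)
  expect_equal(vert$canopy_path_length, 20, tolerance = 0.2)
})

test_that("fixtures survive a GeoTIFF export/import cycle", {
  spec <- fixture_gapped()
  dir <- withr::local_tempdir()
  terr <- make_terrain(spec); fo <- make_forest(spec)
  for (nm in c("local", "regional"))
    write_grid(terr[[nm]], file.path(dir, paste0(nm, ".tif")))
  write_grid(fo$chm, file.path(dir, "chm.tif"))
  write_grid(fo$mask, file.path(dir, "mask.tif"))
  expect_identical(read_grid(file.path(dir, "local.tif"),
                             "elevation")$values, terr$local$values)
  expect_identical(read_grid(file.path(dir, "chm.tif"),
                             "canopy_height")$values, fo$chm$values)
  expect_identical(read_grid(file.path(dir, "mask.tif"),
                             "forest_mask")$values, fo$mask$values)
})
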