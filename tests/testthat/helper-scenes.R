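# Shared fixture builders. Everything is generated in code; scenes are kept
# small (<= 64x64 local cells) so brute-force oracles stay cheap.

fixture_crater <- function() {
  scene_spec("crater", "none", extent = 320, rim_angle = 30, rim_radius = 80,
             local_res = 5, regional_res = 40)
}

fixture_slope <- function(slope = 10, aspect = 0) {
  scene_spec("inclined_plane", "none", extent = 300, slope = slope,
             aspect = aspect, local_res = 5, regional_res = 50)
}

fixture_slab <- function(height = 20) {
  scene_spec("flat", "uniform_slab", extent = 64, crown_height = height,
             local_res = 1, chm_res = 1)
}

fixture_gapped <- function(seed = 3) {
  scene_spec("flat", "gapped", extent = 100, n_crowns = 12, crown_size = 6,
             crown_height = 12, gap_radius = 22, buffer = 12,
             local_res = 5, regional_res = 50, seed = seed)
}

uniform_lambda <- function(chm, lambda) {
  raster_grid(matrix(lambda, nrow(chm$values), ncol(chm$values)),
              chm$resolution, chm$origin, chm$crs_id, kind = "lambda")
}

scene_inputs <- function(spec, cfg = model_config()) {
  terr <- make_terrain(spec)
  fo <- make_forest(spec)
  list(dtm_local = terr$local, dtm_regional = terr$regional,
       chm = fo$chm, mask = fo$mask, mix = fo$mix,
       lambda_on = interpolate_lambda(fo$mix, "leaf_on", cfg,
                                      target = fo$chm),
       lambda_off = interpolate_lambda(fo$mix, "leaf_off", cfg,
                                       target = fo$chm))
}

# uniform-probability transmission field on the standard 90x360 grid
uniform_field_p <- function(p) {
  structure(matrix(p, 90, 360), class = "transmission_field")
}

all_sky_image <- function() hemi_image(matrix(TRUE, 90, 360))

# vertical half-plane wall: one azimuth half obstructed at all zeniths
wall_image <- function() {
  hemi_image(cbind(matrix(TRUE, 90, 180), matrix(FALSE, 90, 180)))
}
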