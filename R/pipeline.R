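## Mask-driven orchestration: terrain-only at every modelled pixel,
## terrain + canopy (leaf-on and leaf-off) at forest pixels.

#' Plan a model run from a forest mask
#'
#' One model point is placed at the centre of every non-zero mask cell.
#' Mask code 1 (forest) receives the full layer set
#' \{terrain, leaf_on, leaf_off\}; code 2 (open) receives \{terrain\};
#' code 0 cells are skipped entirely. Planning is deterministic: re-planning
#' the same mask and config yields an identical manifest.
#'
#' @param mask A forest-mask `hemirad_grid` (codes 0/1/2).
#' @param config A [model_config()].
#' @return A `run_manifest`: data frame with `point_id`, `row`, `col`, `x`,
#'   `y`, `code` and `layers` (comma-separated), with the mask geometry and
#'   a config fingerprint as attributes.
#' @export
plan_run <- function(mask, config = model_config()) {
  stopifnot(inherits(mask, "hemirad_grid"), mask$kind == "forest_mask")
  codes <- mask$values
  sel <- which(!is.na(codes) & codes > 0, arr.ind = TRUE)
  if (nrow(sel) == 0) {
    man <- data.frame(point_id = integer(0), row = integer(0),
                      col = integer(0), x = numeric(0), y = numeric(0),
                      code = integer(0), layers = character(0))
  } else {
    sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    xy <- grid_cell_xy(mask, sel[, 1], sel[, 2])
    code <- codes[sel]
    man <- data.frame(point_id = seq_len(nrow(sel)),
                      row = as.integer(sel[, 1]),
                      col = as.integer(sel[, 2]),
                      x = xy$x, y = xy$y,
                      code = as.integer(code),
                      layers = ifelse(code == 1,
                                      "terrain,leaf_on,leaf_off", "terrain"))
  }
  attr(man, "mask_dim") <- dim(mask$values)
  attr(man, "mask_origin") <- mask$origin
  attr(man, "mask_resolution") <- mask$resolution
  attr(man, "crs_id") <- mask$crs_id
  attr(man, "config_fingerprint") <- config_fingerprint(config)
  class(man) <- c("run_manifest", "data.frame")
  man
}

config_fingerprint <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    collapse = ";", sep = "=")
  ## polynomial rolling hash over the serialised parameter string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 1000000007
  sprintf("%09d", h)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d points (%d forest, %d open), config %s\n",
              nrow(x), sum(x$code == 1), sum(x$code == 2),
              attr(x, "config_fingerprint")))
  invisible(x)
}

#' Run the full model at one point
#'
#' Composes the whole chain at a single model point: two-stage terrain
#' horizon (regional stage alone when the local DTM is missing or nodata
#' there), canopy path-length scan with leaf-on/leaf-off foliage densities,
#' seeded binarisation (leaf layers share per-direction uniform draws, so
#' leaf-on occlusion nests inside leaf-off), image composition, both
#' sky-view factors and the hourly DBT series.
#'
#' @param point Numeric `c(x, y)` in the projected CRS of the inputs.
#' @param layers Character subset of `c("terrain", "leaf_on", "leaf_off")`.
#' @param inputs List with `dtm_local`, `dtm_regional` (elevation grids;
#'   either may be `NULL`), and for leaf layers `chm`, `lambda_on`,
#'   `lambda_off`.
#' @param config A [model_config()].
#' @param days Optional `Date` vector restricting the DBT track.
#' @param point_id Integer identity of the point, used to derive its
#'   binarisation seed (ordering-independent reproducibility).
#' @param dbt Logical; set `FALSE` to skip the DBT series (SVF only).
#' @return A named list per layer, each with `svf_planar`, `svf_hemi`,
#'   `image` (the `hemi_image`) and `dbt` (hourly data frame or `NULL`).
#' @export
run_point <- function(point, layers, inputs, config = model_config(),
                      days = NULL, point_id = 1L, dbt = TRUE) {
  layers <- match.arg(layers, c("terrain", "leaf_on", "leaf_off"),
                      several.ok = TRUE)
  dtm_l <- inputs$dtm_local
  dtm_r <- inputs$dtm_regional
  if (is.null(dtm_l) && is.null(dtm_r))
    stop("at least one DTM is required")

  local_prof <- NULL
  if (!is.null(dtm_l) && grid_contains(dtm_l, point[1], point[2]) &&
      !is.na(grid_bilinear(dtm_l, point[1], point[2]))) {
    local_prof <- horizon_from_grid(dtm_l, point,
                                    min(config$local_radius,
                                        max_ray_radius(dtm_l, point)),
                                    config$azimuth_step,
                                    config$viewer_height)
  }
  regional_prof <- NULL
  if (!is.null(dtm_r) && grid_contains(dtm_r, point[1], point[2]) &&
      !is.na(grid_bilinear(dtm_r, point[1], point[2]))) {
    regional_prof <- horizon_from_grid(dtm_r, point,
                                       min(config$regional_radius,
                                           max_ray_radius(dtm_r, point)),
                                       config$azimuth_step,
                                       config$viewer_height)
  }
  terrain_prof <- if (!is.null(local_prof) && !is.null(regional_prof)) {
    combine_horizons(local_prof, regional_prof)
  } else if (!is.null(local_prof)) local_prof
  else if (!is.null(regional_prof)) regional_prof
  else stop("point has no valid elevation in either DTM")
  terrain_img <- horizon_to_image(terrain_prof, config)

  crs <- if (!is.null(dtm_l)) dtm_l$crs_id else dtm_r$crs_id
  ll <- projected_to_latlon(crs, point[1], point[2])

  out <- list()
  leaf <- intersect(layers, c("leaf_on", "leaf_off"))
  if (length(leaf)) {
    stopifnot(!is.null(inputs$chm), !is.null(inputs$lambda_on),
              !is.null(inputs$lambda_off))
    dtm_for_canopy <- if (!is.null(dtm_l)) dtm_l else dtm_r
    field <- canopy_horizon_and_thickness(
      inputs$chm, dtm_for_canopy, point,
      list(on = inputs$lambda_on, off = inputs$lambda_off), config)
    u <- if (config$binarise == "stochastic")
      uniform_field(dim(field$l), point_seed(config$rng_seed, point_id))
    else NULL
    imgs <- lapply(c(on = 1L, off = 2L), function(k) {
      pf <- structure(list(l = field$l, laml = field$laml[[k]],
                           canopy_top = field$canopy_top),
                      class = "path_length_field")
      p <- transmission_probability(pf, config)
      canopy_img <- binarise_probability(p, uniforms = u,
                                         mode = config$binarise)
      compose_images(terrain_img, canopy_img)
    })
  }

  for (layer in layers) {
    img <- switch(layer, terrain = terrain_img,
                  leaf_on = imgs[["on"]], leaf_off = imgs[["off"]])
    res <- svf_pair(img, config)
    res$image <- img
    res$dbt <- if (dbt) dbt_track(img, ll$lat, ll$lon, config, days)
               else NULL
    out[[layer]] <- res
  }
  out
}

## Largest radius fully usable before leaving the grid is not required --
## rays simply stop at the boundary -- but horizon_from_grid rejects radii
## smaller than a cell, so clamp only to keep the call valid.
max_ray_radius <- function(grid, point) {
  b <- grid_bbox(grid)
  max(grid$resolution,
      max(b[2] - b[1], b[4] - b[3]))
}

#' Run the pipeline over a manifest and write the output files
#'
#' Produces the three-layer output set: per SVF variant and layer one 8-bit
#' encoded GeoTIFF (`svf_<variant>_<layer>.tif`), and per layer and day one
#' daily DBT NetCDF (`dbt_<layer>_<YYYYMMDD>.nc`) holding 24 hourly steps.
#' Open pixels carry nodata in the leaf layers. Existing files are kept
#' unless `overwrite = TRUE`, making an interrupted run resumable; results
#' are independent of evaluation order because each point's binarisation
#' seed derives from its manifest id.
#'
#' @param manifest A `run_manifest` from [plan_run()].
#' @param inputs As in [run_point()].
#' @param output_dir Output directory (created if missing).
#' @param config A [model_config()].
#' @param days `Date` vector of days to compute DBT for; `NULL` runs the
#'   whole configured year.
#' @param verbose Logical; report per-point progress.
#' @param overwrite Logical; recompute and replace existing files.
#' @return Invisibly, the character vector of files written.
#' @export
run_tiles <- function(manifest, inputs, output_dir, config = model_config(),
                      days = NULL, verbose = FALSE, overwrite = FALSE) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dm <- attr(manifest, "mask_dim")
  if (is.null(days)) {
    t0 <- as.Date(sprintf("%d-01-01", config$year))
    t1 <- as.Date(sprintf("%d-12-31", config$year))
    days <- seq(t0, t1, by = "day")
  } else days <- as.Date(days)

  layer_set <- c("terrain", "leaf_on", "leaf_off")
  svf_maps <- list()
  for (layer in layer_set)
    for (variant in c("planar", "hemi"))
      svf_maps[[paste(variant, layer, sep = "_")]] <- matrix(NA_real_,
                                                             dm[1], dm[2])
  dbt_arr <- lapply(layer_set, function(l)
    array(NA_real_, dim = c(24 * length(days), dm[1], dm[2])))
  names(dbt_arr) <- layer_set

  for (i in seq_len(nrow(manifest))) {
    pt <- c(manifest$x[i], manifest$y[i])
    layers <- strsplit(manifest$layers[i], ",")[[1]]
    res <- run_point(pt, layers, inputs, config, days = days,
                     point_id = manifest$point_id[i])
    r <- manifest$row[i]; cc <- manifest$col[i]
    for (layer in layers) {
      svf_maps[[paste("planar", layer, sep = "_")]][r, cc] <-
        res[[layer]]$svf_planar
      svf_maps[[paste("hemi", layer, sep = "_")]][r, cc] <-
        res[[layer]]$svf_hemi
      dbt_arr[[layer]][, r, cc] <- res[[layer]]$dbt$dbt
    }
    if (verbose && (i %% 10 == 0 || i == nrow(manifest)))
      message(sprintf("run_tiles: %d/%d points done", i, nrow(manifest)))
  }

  template <- raster_grid(matrix(0, dm[1], dm[2]),
                          attr(manifest, "mask_resolution"),
                          attr(manifest, "mask_origin"),
                          attr(manifest, "crs_id"), kind = "encoded")
  written <- character(0)
  for (nm in names(svf_maps)) {
    path <- file.path(output_dir, paste0("svf_", nm, ".tif"))
    if (!file.exists(path) || overwrite) {
      enc <- encode_fraction(svf_maps[[nm]])
      g <- raster_grid(enc, template$resolution, template$origin,
                       template$crs_id, kind = "encoded")
      attr(g, "description") <- paste0("kind=encoded;variable=SVF_",
                                       sub("_.*$", "", nm), ";layer=",
                                       sub("^[a-z]+_", "", nm))
      write_grid(g, path)
      written <- c(written, path)
    }
  }
  for (layer in layer_set) {
    if (all(is.na(dbt_arr[[layer]]))) next
    for (di in seq_along(days)) {
      path <- file.path(output_dir,
                        paste0("dbt_", layer, "_",
                               format(days[di], "%Y%m%d"), ".nc"))
      if (file.exists(path) && !overwrite) next
      slab <- dbt_arr[[layer]][(di - 1) * 24 + 1:24, , , drop = FALSE]
      write_dbt_netcdf(slab, days[di], template, path)
      written <- c(written, path)
    }
  }
  invisible(written)
}
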