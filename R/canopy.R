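#' Canopy-top horizon and within-crown path lengths
#'
#' For every (zenith, azimuth) direction of the hemispheric grid, marches a
#' ray from the viewpoint and accumulates the length spent inside canopy
#' volume (between the ground surface and ground + canopy height; the canopy
#' is treated as a vertical column under each CHM cell, since a height model
#' carries no crown-base information). Alongside the plain path length, the
#' path-weighted foliage density `sum(lambda * l)` is accumulated per cell,
#' supporting spatially varying lambda. The canopy-top horizon is the
#' highest elevation angle at which canopy blocks each azimuth.
#'
#' Rays are marched at `config$canopy_ray_step` metres (default 0.5 m, half
#' the nominal 1 m CHM cell) and truncated at `config$max_canopy_range`
#' (default: the local horizon radius) or where they rise above the scene's
#' maximum surface height.
#'
#' @param chm A canopy-height `hemirad_grid` (nominally 1 m resolution).
#' @param dtm An elevation `hemirad_grid` co-registered with `chm` (same
#'   CRS; resolutions may differ).
#' @param point Numeric `c(x, y)` viewpoint inside both grids.
#' @param lambda_grid A lambda `hemirad_grid` co-registered with the CHM, or
#'   a list of such grids (one scan, several weightings - used for leaf-on /
#'   leaf-off). `NA` lambda cells contribute 0.
#' @param config A [model_config()].
#' @return A `path_length_field`: list with `l` (`[nzen, naz]` path-length
#'   matrix, m), `laml` (matrix `sum(lambda*l)`, or list of matrices when
#'   `lambda_grid` is a list), and `canopy_top` (`horizon_profile` of
#'   canopy-top elevation angles, `-90` where no canopy intersects).
#' @export
canopy_horizon_and_thickness <- function(chm, dtm, point, lambda_grid,
                                         config = model_config()) {
  stopifnot(inherits(chm, "hemirad_grid"), inherits(dtm, "hemirad_grid"))
  lams <- if (inherits(lambda_grid, "hemirad_grid")) list(lambda_grid)
          else lambda_grid
  single <- inherits(lambda_grid, "hemirad_grid")
  for (lg in lams) {
    stopifnot(inherits(lg, "hemirad_grid"))
    if (!identical(lg$origin, chm$origin) ||
        !identical(dim(lg$values), dim(chm$values)) ||
        lg$resolution != chm$resolution)
      stop("lambda grid is not co-registered with the canopy height model")
  }
  if (chm$crs_id != dtm$crs_id)
    stop("CHM and DTM are in different CRSs")
  if (!grid_contains(chm, point[1], point[2]) ||
      !grid_contains(dtm, point[1], point[2]))
    stop("point lies outside the canopy or terrain grid")
  zg <- grid_bilinear(dtm, point[1], point[2])
  if (is.na(zg)) stop("ground elevation is nodata at the point")
  nzen <- as.integer(90 / config$zenith_step)
  naz <- as.integer(360 / config$azimuth_step)
  max_surf <- suppressWarnings(max(dtm$values, na.rm = TRUE)) +
    suppressWarnings(max(chm$values, 0, na.rm = TRUE))
  res <- canopy_scan_cpp(dtm$values, dtm$resolution, dtm$origin[1],
                         dtm$origin[2], chm$values, chm$resolution,
                         chm$origin[1], chm$origin[2],
                         lapply(lams, `[[`, "values"),
                         point[1], point[2], zg + config$viewer_height,
                         nzen, naz, config$canopy_ray_step,
                         config$max_canopy_range, max_surf)
  ## top-of-canopy horizon: canopy surface where crowns intersect the
  ## azimuth, terrain horizon elsewhere (no canopy = bare-earth skyline)
  terr <- horizon_scan_cpp(dtm$values, dtm$resolution, dtm$origin[1],
                           dtm$origin[2], point[1], point[2],
                           zg + config$viewer_height,
                           config$max_canopy_range, naz,
                           dtm$resolution / 2)
  terr[is.na(terr)] <- -90
  top <- pmax(res$top, terr, na.rm = TRUE)
  top[is.na(top)] <- -90
  structure(list(l = res$l,
                 laml = if (single) res$laml[[1]] else res$laml,
                 canopy_top = horizon_profile(pmin(top, 90),
                                              config$azimuth_step)),
            class = "path_length_field")
}

#' @export
print.path_length_field <- function(x, ...) {
  cat(sprintf("<path_length_field> %d x %d directions, max path %.1f m\n",
              nrow(x$l), ncol(x$l), max(x$l)))
  invisible(x)
}

#' Canopy transmission probability per direction
#'
#' Applies the exponential light-penetration law
#' `p = exp(-G * sum(lambda * l))` to a path-length field: the probability
#' that a beam from the given direction reaches the viewpoint without being
#' intercepted, under projection function `G` (0.5 for randomly oriented
#' foliage) and effective foliage area volume density `lambda` (m^-1)
#' accumulated over all crowns the path intersects.
#'
#' @param path_field A `path_length_field` with a single `laml` matrix.
#' @param config A [model_config()] supplying `G`.
#' @return A `transmission_field`: matrix of probabilities in `[0, 1]` with
#'   `p = 1` wherever the path is canopy-free.
#' @examples
#' # G = 0.5, lambda = 0.5 m^-1, l = 2 m: p = exp(-0.5)
#' f <- structure(list(l = matrix(2, 90, 360),
#'                     laml = matrix(1, 90, 360)),
#'                class = "path_length_field")
#' transmission_probability(f, model_config())[1, 1]
#' @export
transmission_probability <- function(path_field, config = model_config()) {
  laml <- path_field$laml
  if (is.list(laml))
    stop("path field carries multiple lambda weightings; pick one")
  if (any(laml < 0)) stop("negative accumulated lambda*l")
  p <- exp(-config$G * laml)
  structure(p, class = "transmission_field")
}

#' Binarise a transmission field into a canopy hemispheric image
#'
#' Each direction is marked sky with probability `p`. In `"stochastic"` mode
#' the draw uses a dedicated seeded RNG stream (same seed, same image); a
#' pre-drawn uniform field can be supplied so that several probability
#' fields (e.g. leaf-on and leaf-off at the same point) share per-direction
#' draws, which preserves their nesting direction by direction. In
#' `"threshold"` mode a direction is sky iff `p >= 0.5` (deterministic, for
#' regression tests).
#'
#' @param field A `transmission_field` (or plain probability matrix).
#' @param rng_seed Integer seed for the stochastic draw (ignored when
#'   `uniforms` is given).
#' @param uniforms Optional matrix of pre-drawn U(0,1) values, same shape as
#'   `field`; a direction is sky iff `u < p`.
#' @param mode `"stochastic"` or `"threshold"`.
#' @return A `hemi_image` (canopy component).
#' @export
binarise_probability <- function(field, rng_seed = 1L, uniforms = NULL,
                                 mode = c("stochastic", "threshold")) {
  mode <- match.arg(mode)
  p <- unclass(field)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (mode == "threshold") {
    sky <- p >= 0.5
  } else {
    if (is.null(uniforms)) uniforms <- uniform_field(dim(p), rng_seed)
    stopifnot(all(dim(uniforms) == dim(p)))
    sky <- uniforms < p
  }
  hemi_image(sky, 90 / nrow(p), 360 / ncol(p))
}

## Seeded U(0,1) field drawn from an isolated RNG stream (the caller's
## .Random.seed is left untouched).
uniform_field <- function(dm, seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(as.integer(seed))
  matrix(runif(prod(dm)), dm[1], dm[2])
}

## Deterministic per-point seed so that tiling and evaluation order do not
## change results; kept below 2^31.
point_seed <- function(global_seed, point_id) {
  as.integer((as.double(global_seed) * 1000003 +
              as.double(point_id) * 7919) %% 2147483629) + 1L
}

#' Compose terrain and canopy hemispheric images
#'
#' A direction is sky in the composed image iff it is sky in *both* inputs:
#' terrain occlusion and canopy occlusion are independent and both must be
#' absent.
#'
#' @param terrain,canopy `hemi_image`s on the same angular grid.
#' @return A `hemi_image`.
#' @export
compose_images <- function(terrain, canopy) {
  if (!all(dim(terrain) == dim(canopy)))
    stop("hemispheric images are on different angular grids")
  hemi_image(unclass(terrain) & unclass(canopy),
             attr(terrain, "zenith_step"), attr(terrain, "azimuth_step"))
}
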