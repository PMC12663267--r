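## Synthetic scenes: parametric terrain surfaces and procedurally placed
## crowns with closed-form geometry, so every model stage can be checked
## against an analytic ray-marching oracle without any external data.

#' Specify a synthetic scene
#'
#' Terrain kinds: `flat` (constant `z0`); `inclined_plane` (slope
#' `slope` degrees dipping towards azimuth `aspect`); `crater` (flat floor
#' at `z0`, annular plateau beyond `rim_radius` whose rim subtends exactly
#' `rim_angle` degrees from the scene centre); `gaussian_hills` (seeded sum
#' of Gaussian bumps). Forest kinds: `none`, `single_crown`,
#' `uniform_slab`, `plantation` (square lattice) and `gapped` (seeded
#' uniform crown placement with a clear gap of radius `gap_radius` around
#' the scene centre). Crowns are cuboids: full canopy height over a square
#' footprint, consistent with a canopy height model.
#'
#' @param terrain_kind,forest_kind Scene components (see above).
#' @param extent Side length of the square scene in metres.
#' @param z0 Base elevation (m a.s.l.).
#' @param slope,aspect Inclined-plane parameters (degrees).
#' @param rim_angle,rim_radius Crater parameters (degrees / m;
#'   `rim_radius` defaults to `extent / 4`).
#' @param n_hills,hill_height,hill_width Gaussian-hill parameters.
#' @param crown_height,crown_size Crown cuboid height and footprint side
#'   (m).
#' @param crown_offset Single-crown centre offset `c(dx, dy)` from the
#'   scene centre (m).
#' @param spacing Plantation lattice spacing (m).
#' @param n_crowns Number of crowns for `gapped` placement.
#' @param gap_radius Clear-gap radius around the scene centre (m).
#' @param mix Evergreen fraction written into the mix-rate grid.
#' @param local_res,regional_res,chm_res Grid resolutions (m).
#' @param regional_extent Side length of the regional DTM (m; defaults to
#'   `extent`).
#' @param buffer Forest-mask edge buffer distance (m).
#' @param seed Integer seed for the procedural components.
#' @param crs_id Projected CRS of all generated grids.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(terrain_kind = c("flat", "inclined_plane", "crater",
                                        "gaussian_hills"),
                       forest_kind = c("none", "single_crown", "plantation",
                                       "uniform_slab", "gapped"),
                       extent = 200, z0 = 500,
                       slope = 10, aspect = 0,
                       rim_angle = 30, rim_radius = extent / 4,
                       n_hills = 5, hill_height = 30, hill_width = extent / 8,
                       crown_height = 15, crown_size = 5,
                       crown_offset = c(0, 20),
                       spacing = 10, n_crowns = 60, gap_radius = 20,
                       mix = 0.5,
                       local_res = 5, regional_res = 50, chm_res = 1,
                       regional_extent = extent, buffer = 25,
                       seed = 1L, crs_id = "LOCAL:46.8,9.8") {
  spec <- list(terrain_kind = match.arg(terrain_kind),
               forest_kind = match.arg(forest_kind),
               extent = extent, z0 = z0, slope = slope, aspect = aspect,
               rim_angle = rim_angle, rim_radius = rim_radius,
               n_hills = n_hills, hill_height = hill_height,
               hill_width = hill_width,
               crown_height = crown_height, crown_size = crown_size,
               crown_offset = crown_offset, spacing = spacing,
               n_crowns = n_crowns, gap_radius = gap_radius, mix = mix,
               local_res = local_res, regional_res = regional_res,
               chm_res = chm_res, regional_extent = regional_extent,
               buffer = buffer, seed = as.integer(seed), crs_id = crs_id)
  stopifnot(extent > 0, local_res > 0, regional_res > 0, chm_res > 0,
            rim_radius < extent / 2, crown_size > 0)
  class(spec) <- "scene_spec"
  spec
}

scene_centre <- function(spec) c(spec$extent / 2, spec$extent / 2)

## Analytic terrain surface z(x, y); vectorised.
terrain_z <- function(spec, x, y) {
  ctr <- scene_centre(spec)
  switch(spec$terrain_kind,
    flat = rep(spec$z0, length(x)),
    inclined_plane = {
      a <- spec$aspect * pi / 180
      ## surface dips towards `aspect`: height increases opposite to it
      spec$z0 - tan(spec$slope * pi / 180) *
        ((x - ctr[1]) * sin(a) + (y - ctr[2]) * cos(a))
    },
    crater = {
      r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
      spec$z0 + ifelse(r >= spec$rim_radius,
                       tan(spec$rim_angle * pi / 180) * spec$rim_radius, 0)
    },
    gaussian_hills = {
      state <- scene_rng(spec$seed, 101L)
      cx <- state$runif(spec$n_hills, 0, spec$extent)
      cy <- state$runif(spec$n_hills, 0, spec$extent)
      z <- rep(spec$z0, length(x))
      for (i in seq_len(spec$n_hills))
        z <- z + spec$hill_height *
          exp(-((x - cx[i])^2 + (y - cy[i])^2) / (2 * spec$hill_width^2))
      z
    })
}

## Namespaced RNG stream per fixture component: every call replays the same
## isolated stream (seed + stream id), advancing an internal counter, and
## leaves the caller's .Random.seed untouched.
scene_rng <- function(seed, stream) {
  drawn <- 0L
  list(runif = function(n, a = 0, b = 1) {
    saved <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(saved))
      assign(".Random.seed", saved, envir = globalenv()))
    set.seed(seed + 97L * stream)
    if (drawn > 0L) runif(drawn)        # replay past draws
    res <- runif(n, a, b)
    drawn <<- drawn + n
    res
  })
}

## Crown list: data.frame x, y (centre), w (footprint side), h (height)
scene_crowns <- function(spec) {
  ctr <- scene_centre(spec)
  switch(spec$forest_kind,
    none = ,
    uniform_slab = data.frame(x = numeric(0), y = numeric(0),
                              w = numeric(0), h = numeric(0)),
    single_crown = data.frame(x = ctr[1] + spec$crown_offset[1],
                              y = ctr[2] + spec$crown_offset[2],
                              w = spec$crown_size, h = spec$crown_height),
    plantation = {
      ks <- seq(spec$spacing / 2, spec$extent - 1e-9, by = spec$spacing)
      g <- expand.grid(x = ks, y = ks)
      data.frame(x = g$x, y = g$y, w = spec$crown_size,
                 h = spec$crown_height)
    },
    gapped = {
      rng <- scene_rng(spec$seed, 7L)
      xs <- ys <- numeric(0)
      tries <- 0
      while (length(xs) < spec$n_crowns && tries < 50) {
        need <- spec$n_crowns - length(xs)
        cx <- rng$runif(4 * need + 8, spec$crown_size,
                        spec$extent - spec$crown_size)
        cy <- rng$runif(4 * need + 8, spec$crown_size,
                        spec$extent - spec$crown_size)
        keep <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2) > spec$gap_radius
        xs <- c(xs, cx[keep])[seq_len(min(spec$n_crowns,
                                          length(xs) + sum(keep)))]
        ys <- c(ys, cy[keep])[seq_len(length(xs))]
        tries <- tries + 1
      }
      data.frame(x = xs, y = ys, w = spec$crown_size, h = spec$crown_height)
    })
}

## Analytic canopy height h(x, y).
canopy_h <- function(spec, x, y) {
  if (spec$forest_kind == "none") return(rep(0, length(x)))
  if (spec$forest_kind == "uniform_slab") return(rep(spec$crown_height,
                                                     length(x)))
  cr <- scene_crowns(spec)
  h <- rep(0, length(x))
  for (i in seq_len(nrow(cr))) {
    inside <- abs(x - cr$x[i]) <= cr$w[i] / 2 & abs(y - cr$y[i]) <= cr$w[i] / 2
    h[inside] <- pmax(h[inside], cr$h[i])
  }
  h
}

#' Generate local and regional elevation grids for a scene
#'
#' Samples the scene's analytic terrain surface at cell centres of a local
#' (fine) and a regional (coarse, possibly larger) grid. Regeneration with
#' the same spec is bitwise identical.
#'
#' @param spec A [scene_spec()].
#' @return A list with elevation grids `local` and `regional`.
#' @export
make_terrain <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  mk <- function(res, extent, off) {
    n <- as.integer(round(extent / res))
    if (n < 1) stop("degenerate extent")
    xs <- off + (seq_len(n) - 0.5) * res
    ys <- off + extent - (seq_len(n) - 0.5) * res
    g <- expand.grid(x = xs, y = ys)           # column-major: x fastest
    z <- terrain_z(spec, g$x, g$y)
    raster_grid(matrix(z, n, n, byrow = TRUE), res, c(off, off + extent),
                spec$crs_id, kind = "elevation")
  }
  off_reg <- (spec$extent - spec$regional_extent) / 2
  list(local = mk(spec$local_res, spec$extent, 0),
       regional = mk(spec$regional_res, spec$regional_extent, off_reg))
}

#' Generate canopy, mix-rate and forest-mask grids for a scene
#'
#' The canopy height grid samples the analytic crown set at `chm_res`; the
#' mix-rate grid is constant at `spec$mix`; the forest mask is 1 within
#' `spec$buffer` metres of any crown footprint (the forest-edge buffer), 2
#' elsewhere.
#'
#' @param spec A [scene_spec()].
#' @return A list with grids `chm`, `mix` and `mask`.
#' @export
make_forest <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- as.integer(round(spec$extent / spec$chm_res))
  xs <- (seq_len(n) - 0.5) * spec$chm_res
  ys <- spec$extent - (seq_len(n) - 0.5) * spec$chm_res
  g <- expand.grid(x = xs, y = ys)
  chm_v <- canopy_h(spec, g$x, g$y)
  chm <- raster_grid(matrix(chm_v, n, n, byrow = TRUE), spec$chm_res,
                     c(0, spec$extent), spec$crs_id, kind = "canopy_height")

  nm <- max(1L, as.integer(round(spec$extent / 10)))
  mix <- raster_grid(matrix(spec$mix, nm, nm), 10, c(0, spec$extent),
                     spec$crs_id, kind = "mixrate")

  mx <- (seq_len(nm) - 0.5) * 10
  my <- spec$extent - (seq_len(nm) - 0.5) * 10
  mg <- expand.grid(x = mx, y = my)
  mask_v <- rep(2, nrow(mg))
  if (spec$forest_kind == "uniform_slab") {
    mask_v[] <- 1
  } else if (spec$forest_kind != "none") {
    cr <- scene_crowns(spec)
    near <- rep(FALSE, nrow(mg))
    for (i in seq_len(nrow(cr))) {
      dx <- pmax(abs(mg$x - cr$x[i]) - cr$w[i] / 2, 0)
      dy <- pmax(abs(mg$y - cr$y[i]) - cr$w[i] / 2, 0)
      near <- near | (sqrt(dx^2 + dy^2) <= spec$buffer)
    }
    mask_v[near] <- 1
  }
  mask <- raster_grid(matrix(mask_v, nm, nm, byrow = TRUE), 10,
                      c(0, spec$extent), spec$crs_id, kind = "forest_mask")
  list(chm = chm, mix = mix, mask = mask)
}

#' Brute-force visibility oracle for a synthetic scene
#'
#' Marches a single direction densely (default 0.1 m steps) against the
#' scene's *analytic* surfaces, independent of any raster sampling, and
#' reports whether terrain blocks the direction and the exact (to one step)
#' within-canopy path length.
#'
#' @param spec A [scene_spec()].
#' @param point Numeric `c(x, y)` viewpoint.
#' @param zenith,azimuth Direction in degrees (azimuth clockwise from
#'   north).
#' @param step March step in metres.
#' @param max_range Maximum ray length in metres.
#' @param viewer_height Viewpoint height above the terrain surface (m).
#' @return A list `free` (logical: no terrain obstruction),
#'   `terrain_blocked` (logical) and `canopy_path_length` (m).
#' @export
oracle_visibility <- function(spec, point, zenith, azimuth, step = 0.1,
                              max_range = 300, viewer_height = 0) {
  stopifnot(inherits(spec, "scene_spec"), zenith >= 0, zenith <= 90)
  zv <- terrain_z(spec, point[1], point[2]) + viewer_height
  t <- zenith * pi / 180; a <- azimuth * pi / 180
  s <- seq(step, max_range, by = step)
  hx <- point[1] + s * sin(t) * sin(a)
  hy <- point[2] + s * sin(t) * cos(a)
  h <- zv + s * cos(t)
  gz <- terrain_z(spec, hx, hy)
  blocked <- any(h < gz - 1e-9)
  ch <- canopy_h(spec, hx, hy)
  inside <- ch > 0 & h >= gz & h <= gz + ch
  list(free = !blocked, terrain_blocked = blocked,
       canopy_path_length = sum(inside) * step)
}

#' Brute-force terrain horizon oracle
#'
#' Dense ray marching (default 0.1 m) against the analytic terrain surface;
#' returns the maximum elevation angle per azimuth, like
#' [horizon_from_grid()] but free of raster discretisation.
#'
#' @inheritParams oracle_visibility
#' @param azimuths Azimuth angles in degrees (defaults to the 360 standard
#'   bin centres).
#' @param radius Maximum horizontal search distance (m).
#' @return Numeric vector of elevation angles (degrees).
#' @export
oracle_horizon <- function(spec, point, azimuths = (1:360) - 0.5,
                           radius = 300, step = 0.1, viewer_height = 0) {
  zv <- terrain_z(spec, point[1], point[2]) + viewer_height
  d <- seq(step, radius, by = step)
  vapply(azimuths, function(az) {
    a <- az * pi / 180
    gz <- terrain_z(spec, point[1] + d * sin(a), point[2] + d * cos(a))
    max(atan2(gz - zv, d)) * 180 / pi
  }, numeric(1))
}
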