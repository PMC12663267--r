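#' Model configuration
#'
#' Collects every tunable parameter of the hemispheric-image radiation model
#' in one validated object. Defaults reproduce the standard model setup:
#' a two-stage terrain horizon (5 m DTM out to 300 m, 50 m DTM out to 25 km),
#' 1 degree angular resolution, 10 degree sky-view-factor zenith rings, a
#' 0.53 degree solar disc tracked at 2-minute cadence, and a projection
#' function G = 0.5 for randomly oriented foliage.
#'
#' The foliage density values (`lambda_*`, units m^-1) are *uncalibrated
#' placeholders*: calibrating them requires segmented lidar tree crowns and
#' species allometry, which are inputs to this package, not outputs. Replace
#' them with site-calibrated values for real-world use. The leaf-on larch
#' default equals the evergreen default (larch crowns in leaf are about as
#' dense as spruce); leaf-off deciduous values are much smaller because only
#' woody elements remain.
#'
#' @param local_radius Search radius (m) for the local-stage terrain horizon.
#' @param regional_radius Search radius (m) for the regional-stage horizon.
#' @param azimuth_step Azimuthal bin width in degrees; must divide 360.
#' @param zenith_step Zenith bin width in degrees; must divide 90.
#' @param solar_disc_diameter Apparent diameter of the solar disc in degrees.
#' @param G Projection function value for foliage orientation (0.5 = random).
#' @param lambda_evergreen,lambda_deciduous_on,lambda_deciduous_off,lambda_larch_on,lambda_larch_off
#'   Effective foliage area volume density endpoints (m^-1) per forest type
#'   and leaf condition.
#' @param rng_seed Integer seed governing the stochastic binarisation.
#' @param svf_ring_width Zenith ring width (degrees) for sky-view factors;
#'   must divide 90.
#' @param track_step Solar track cadence in minutes; must divide 60.
#' @param viewer_height Height of the viewpoint above the ground surface (m).
#' @param canopy_ray_step Step length (m) for ray marching through the canopy.
#' @param max_canopy_range Hard cap (m) on canopy ray length; defaults to the
#'   local horizon radius.
#' @param binarise Either `"stochastic"` (seeded Bernoulli draw per direction)
#'   or `"threshold"` (deterministic sky iff p >= 0.5).
#' @param refraction Logical; apply the NOAA atmospheric refraction correction
#'   to solar elevation. Off by default (potential, not observed, geometry).
#' @param disc_grid Number of sample offsets per axis used to supersample the
#'   solar disc (odd integer; the disc is smaller than one image cell, so
#'   supersampling recovers partial occlusion).
#' @param year Calendar year of the solar track (2020 = leap year, 8784 h).
#'
#' @return An object of class `hemirad_config` (a validated named list).
#' @examples
#' cfg <- model_config()
#' cfg$G
#' @export
model_config <- function(local_radius = 300,
                         regional_radius = 25000,
                         azimuth_step = 1,
                         zenith_step = 1,
                         solar_disc_diameter = 0.53,
                         G = 0.5,
                         lambda_evergreen = 0.6,
                         lambda_deciduous_on = 0.5,
                         lambda_deciduous_off = 0.15,
                         lambda_larch_on = lambda_evergreen,
                         lambda_larch_off = 0.15,
                         rng_seed = 1L,
                         svf_ring_width = 10,
                         track_step = 2,
                         viewer_height = 0,
                         canopy_ray_step = 0.5,
                         max_canopy_range = local_radius,
                         binarise = c("stochastic", "threshold"),
                         refraction = FALSE,
                         disc_grid = 11L,
                         year = 2020L) {
  binarise <- match.arg(binarise)
  stopifnot(local_radius > 0, regional_radius > 0,
            solar_disc_diameter > 0, G > 0, G <= 1,
            canopy_ray_step > 0, max_canopy_range > 0,
            viewer_height >= 0, disc_grid >= 3)
  if (360 %% azimuth_step != 0)
    stop("azimuth_step must divide 360")
  if (90 %% zenith_step != 0)
    stop("zenith_step must divide 90")
  if (90 %% svf_ring_width != 0)
    stop("svf_ring_width must divide 90")
  if (60 %% track_step != 0)
    stop("track_step must divide 60")
  lam <- c(lambda_evergreen, lambda_deciduous_on, lambda_deciduous_off,
           lambda_larch_on, lambda_larch_off)
  if (any(lam < 0)) stop("lambda values must be >= 0")
  cfg <- list(local_radius = local_radius,
              regional_radius = regional_radius,
              azimuth_step = azimuth_step,
              zenith_step = zenith_step,
              solar_disc_diameter = solar_disc_diameter,
              G = G,
              lambda_evergreen = lambda_evergreen,
              lambda_deciduous_on = lambda_deciduous_on,
              lambda_deciduous_off = lambda_deciduous_off,
              lambda_larch_on = lambda_larch_on,
              lambda_larch_off = lambda_larch_off,
              rng_seed = as.integer(rng_seed),
              svf_ring_width = svf_ring_width,
              track_step = track_step,
              viewer_height = viewer_height,
              canopy_ray_step = canopy_ray_step,
              max_canopy_range = max_canopy_range,
              binarise = binarise,
              refraction = refraction,
              disc_grid = as.integer(disc_grid),
              year = as.integer(year))
  class(cfg) <- "hemirad_config"
  cfg
}

#' @export
print.hemirad_config <- function(x, ...) {
  cat("<hemirad_config>\n")
  cat(sprintf("  horizon: local %g m, regional %g m; %g deg azimuth x %g deg zenith\n",
              x$local_radius, x$regional_radius, x$azimuth_step, x$zenith_step))
  cat(sprintf("  canopy: G = %g, ray step %g m (cap %g m), binarise = %s\n",
              x$G, x$canopy_ray_step, x$max_canopy_range, x$binarise))
  cat(sprintf("  lambda (m^-1): evergreen %g | deciduous on %g / off %g | larch on %g / off %g\n",
              x$lambda_evergreen, x$lambda_deciduous_on, x$lambda_deciduous_off,
              x$lambda_larch_on, x$lambda_larch_off))
  cat(sprintf("  solar: year %d, %g-min track, %g deg disc, refraction %s\n",
              x$year, x$track_step, x$solar_disc_diameter, x$refraction))
  cat(sprintf("  SVF rings: %g deg; seed %d\n", x$svf_ring_width, x$rng_seed))
  invisible(x)
}
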