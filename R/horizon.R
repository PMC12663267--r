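#' Terrain horizon profile around a point
#'
#' Scans rays at regular azimuthal increments (clockwise from north, bin
#' centres at half-steps) and returns, per azimuth, the maximum terrain
#' elevation angle `atan((z - z_viewer) / d)` over samples along the ray out
#' to `radius`. Rays are sampled at half-cell intervals with bilinear
#' elevation interpolation. Angles are returned as computed (they may be
#' negative when all terrain lies below the viewer); conversion to a
#' hemispheric image applies the sky/obstructed floor of 0.
#'
#' @param dtm An elevation `hemirad_grid`.
#' @param point Numeric `c(x, y)` in the grid's projected CRS.
#' @param radius Search radius in metres (at least one cell).
#' @param azimuth_step Azimuth bin width in degrees (must divide 360).
#' @param viewer_height Viewpoint height above the ground surface (m).
#' @return A `horizon_profile`: numeric vector of elevation angles (degrees),
#'   one per azimuth bin, with attribute `azimuth` (bin centres, degrees
#'   clockwise from north).
#' @examples
#' flat <- raster_grid(matrix(500, 40, 40), 5, c(0, 200))
#' h <- horizon_from_grid(flat, c(100, 100), radius = 80)
#' range(h)
#' @export
horizon_from_grid <- function(dtm, point, radius, azimuth_step = 1,
                              viewer_height = 0) {
  stopifnot(inherits(dtm, "hemirad_grid"), length(point) == 2)
  if (!grid_contains(dtm, point[1], point[2]))
    stop("point lies outside the elevation grid")
  if (radius < dtm$resolution)
    stop("radius must cover at least one grid cell")
  if (360 %% azimuth_step != 0) stop("azimuth_step must divide 360")
  zg <- grid_bilinear(dtm, point[1], point[2])
  if (is.na(zg))
    stop("elevation is nodata at the point; use the regional profile alone")
  naz <- as.integer(360 / azimuth_step)
  ang <- horizon_scan_cpp(dtm$values, dtm$resolution, dtm$origin[1],
                          dtm$origin[2], point[1], point[2],
                          zg + viewer_height, radius, naz,
                          dtm$resolution / 2)
  ang[is.na(ang)] <- -90   # no valid sample along the ray: open to the sky
  horizon_profile(ang, azimuth_step)
}

#' Construct a horizon profile from elevation angles
#'
#' @param angles Numeric vector of elevation angles in degrees, one per
#'   azimuth bin (clockwise from north, bin centres at half-steps), each in
#'   `[-90, 90]`.
#' @param azimuth_step Azimuth bin width in degrees.
#' @return A `horizon_profile`.
#' @export
horizon_profile <- function(angles, azimuth_step = 360 / length(angles)) {
  stopifnot(length(angles) == 360 / azimuth_step,
            all(angles >= -90 & angles <= 90))
  structure(as.numeric(angles),
            azimuth = (seq_along(angles) - 0.5) * azimuth_step,
            azimuth_step = azimuth_step,
            class = "horizon_profile")
}

#' @export
print.horizon_profile <- function(x, ...) {
  cat(sprintf("<horizon_profile> %d azimuth bins (%g deg), angles [%0.2f, %0.2f] deg\n",
              length(x), attr(x, "azimuth_step"), min(x), max(x)))
  invisible(x)
}

#' Combine local and regional horizon profiles
#'
#' The two-stage terrain horizon takes the per-azimuth maximum of the
#' local-stage (fine DTM, small radius) and regional-stage (coarse DTM,
#' large radius) profiles.
#'
#' @param local,regional `horizon_profile` objects on the same azimuth grid.
#' @return A `horizon_profile`.
#' @export
combine_horizons <- function(local, regional) {
  if (length(local) != length(regional))
    stop("horizon profiles have different azimuth resolutions")
  horizon_profile(pmax(as.numeric(local), as.numeric(regional)),
                  attr(local, "azimuth_step"))
}

#' Binary hemispheric image
#'
#' A hemispheric image is a logical matrix over a regular
#' (zenith, azimuth) grid covering zenith `[0, 90)` x azimuth `[0, 360)`
#' with bin centres at half-steps; `TRUE` = sky, `FALSE` = obstructed.
#' When rendered (see [plot.hemi_image()]) images are oriented south-up,
#' east-right, as an upward-looking fisheye photograph.
#'
#' @param sky Logical matrix `[nzen, naz]`.
#' @param zenith_step,azimuth_step Bin widths in degrees.
#' @return A `hemi_image`.
#' @export
hemi_image <- function(sky, zenith_step = 90 / nrow(sky),
                       azimuth_step = 360 / ncol(sky)) {
  sky <- as.matrix(sky)
  storage.mode(sky) <- "logical"
  stopifnot(nrow(sky) == 90 / zenith_step, ncol(sky) == 360 / azimuth_step,
            !anyNA(sky))
  structure(sky, zenith_step = zenith_step, azimuth_step = azimuth_step,
            class = "hemi_image")
}

#' @export
print.hemi_image <- function(x, ...) {
  cat(sprintf("<hemi_image> %d x %d (zenith x azimuth), sky fraction %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

zenith_centres <- function(image) {
  zs <- attr(image, "zenith_step")
  (seq_len(nrow(image)) - 0.5) * zs
}

#' Convert a horizon profile to a terrain-only hemispheric image
#'
#' A direction with zenith-bin centre `z` and azimuth `a` is sky iff its
#' elevation angle `90 - z` exceeds the horizon angle at `a` (negative
#' horizon angles are floored at 0: terrain below the viewer never opens the
#' lower hemisphere).
#'
#' @param horizon A `horizon_profile`.
#' @param config A [model_config()] (for the angular steps).
#' @return A `hemi_image` whose columns are monotone: sky above the horizon,
#'   obstructed below.
#' @export
horizon_to_image <- function(horizon, config = model_config()) {
  nzen <- as.integer(90 / config$zenith_step)
  naz <- as.integer(360 / config$azimuth_step)
  if (length(horizon) != naz)
    stop("horizon profile resolution does not match config$azimuth_step")
  h <- pmax(as.numeric(horizon), 0)
  zc <- (seq_len(nzen) - 0.5) * config$zenith_step
  elev <- 90 - zc
  sky <- outer(elev, h, ">")
  hemi_image(sky, config$zenith_step, config$azimuth_step)
}

#' Render a hemispheric image as an upward-looking fisheye view
#'
#' Equiangular polar rendering, oriented south-up and east-right. Intended
#' for visual inspection of synthetic images.
#'
#' @param x A `hemi_image`.
#' @param sky_col,obstructed_col Fill colours.
#' @param ... Ignored.
#' @export
plot.hemi_image <- function(x, sky_col = "white", obstructed_col = "grey20",
                            ...) {
  zs <- attr(x, "zenith_step"); as <- attr(x, "azimuth_step")
  plot.new()
  plot.window(c(-1.1, 1.1), c(-1.1, 1.1), asp = 1)
  th <- seq(0, 2 * pi, length.out = 181)
  polygon(sin(th), cos(th), col = obstructed_col, border = NA)
  for (zi in rev(seq_len(nrow(x)))) {
    r0 <- (zi - 1) * zs / 90; r1 <- zi * zs / 90
    for (ai in seq_len(ncol(x))) {
      if (!x[zi, ai]) next
      a0 <- (ai - 1) * as; a1 <- ai * as
      ## screen angle: south (az 180) up, east (az 90) right
      chi <- (180 - seq(a0, a1, length.out = 5)) * pi / 180
      px <- c(r0 * sin(chi), r1 * sin(rev(chi)))
      py <- c(r0 * cos(chi), r1 * cos(rev(chi)))
      polygon(px, py, col = sky_col, border = NA)
    }
  }
  lines(sin(th), cos(th))
  text(0, 1.06, "S"); text(0, -1.06, "N")
  text(1.06, 0, "E"); text(-1.06, 0, "W")
  invisible(x)
}
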