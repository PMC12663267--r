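#' Solid-angle-weighted sky fraction of a zenith ring
#'
#' The fraction of sky within a zenith interval, with each 1-degree cell
#' weighted by its solid angle (proportional to `sin` of the cell's zenith
#' centre). On the (zenith, azimuth) grid this reproduces the pixel ratio of
#' a rendered hemispherical image without committing to a projection.
#'
#' @param image A `hemi_image`.
#' @param ring Numeric `c(zenith_from, zenith_to)` in degrees, aligned to the
#'   image's zenith bins.
#' @return Sky fraction in `[0, 1]`.
#' @export
ring_sky_fraction <- function(image, ring) {
  zs <- attr(image, "zenith_step")
  stopifnot(length(ring) == 2, ring[1] < ring[2], ring[1] >= 0, ring[2] <= 90)
  if (ring[1] %% zs != 0 || ring[2] %% zs != 0)
    stop("ring edges must align with the image's zenith bins")
  zc <- zenith_centres(image)
  rows <- which(zc > ring[1] & zc < ring[2])
  w <- sin(zc[rows] * pi / 180)
  sum(w * rowMeans(unclass(image)[rows, , drop = FALSE])) / sum(w)
}

svf_rings <- function(config) {
  edges <- seq(0, 90, by = config$svf_ring_width)
  cbind(from = edges[-length(edges)], to = edges[-1])
}

#' Sky-view factor, planar-receiver variant
#'
#' Weights each zenith ring's sky fraction by the ring's surface area
#' projected onto a horizontal plane: for a ring `[t1, t2)` the analytic
#' weight is `sin^2(t2) - sin^2(t1)` (weights sum to 1 over the hemisphere).
#' This is the diffuse-light proxy seen by a flat ground or snow surface.
#'
#' @param image A `hemi_image`.
#' @param config A [model_config()] supplying the ring width (default 10
#'   degrees).
#' @return A fraction in `[0, 1]`.
#' @examples
#' cfg <- model_config()
#' img <- horizon_to_image(horizon_profile(rep(30, 360)), cfg)
#' svf_planar(img, cfg)  # sin^2(60 deg) = 0.75
#' svf_hemi(img, cfg)    # 1 - cos(60 deg) = 0.5
#' @export
svf_planar <- function(image, config = model_config()) {
  rings <- svf_rings(config)
  rad <- pi / 180
  w <- sin(rings[, "to"] * rad)^2 - sin(rings[, "from"] * rad)^2
  f <- apply(rings, 1, function(r) ring_sky_fraction(image, r))
  sum(w * f) / sum(w)
}

#' Sky-view factor, hemispheric-receiver variant
#'
#' Weights each zenith ring's sky fraction by the ring's surface area on the
#' hemisphere itself: for a ring `[t1, t2)` the analytic weight is
#' `cos(t1) - cos(t2)`. This is the perspective of a three-dimensional
#' object such as a plant.
#'
#' @inheritParams svf_planar
#' @return A fraction in `[0, 1]`.
#' @export
svf_hemi <- function(image, config = model_config()) {
  rings <- svf_rings(config)
  rad <- pi / 180
  w <- cos(rings[, "from"] * rad) - cos(rings[, "to"] * rad)
  f <- apply(rings, 1, function(r) ring_sky_fraction(image, r))
  sum(w * f) / sum(w)
}

#' Both sky-view-factor variants at once
#'
#' @inheritParams svf_planar
#' @return A list with elements `svf_planar` and `svf_hemi`.
#' @export
svf_pair <- function(image, config = model_config()) {
  list(svf_planar = svf_planar(image, config),
       svf_hemi = svf_hemi(image, config))
}
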