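## Georeferenced grid containers.
##
## A hemirad_grid is a plain numeric matrix plus georeferencing: rows run
## north -> south (row 1 is the northernmost), columns west -> east, `origin`
## is the (xmin, ymax) corner of the top-left cell, `resolution` the square
## cell size in metres. Coordinates are in a projected metric CRS identified
## by a string: "EPSG:<code>" or "LOCAL:<lat>,<lon>" (a local tangent plane
## anchored at the given geographic point, used by the synthetic scenes).

#' Construct a georeferenced grid
#'
#' @param values Numeric matrix; row 1 is the northernmost row. `NA` encodes
#'   nodata.
#' @param resolution Cell size in metres (> 0).
#' @param origin Length-2 numeric `c(xmin, ymax)`: projected coordinates of
#'   the outer corner of the top-left cell.
#' @param crs_id CRS identifier string, e.g. `"EPSG:2056"` or
#'   `"LOCAL:46.8,9.8"`. Geographic (degree-unit) CRSs are rejected because
#'   all model geometry works in metres.
#' @param kind Grid kind: `"elevation"`, `"canopy_height"`, `"forest_mask"`,
#'   `"mixrate"`, `"lambda"` or `"encoded"`.
#'
#' @return An object of class `hemirad_grid`.
#' @export
raster_grid <- function(values, resolution, origin, crs_id = "LOCAL:46.8,9.8",
                        kind = "elevation") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(resolution), length(resolution) == 1, resolution > 0,
            length(origin) == 2, is.character(crs_id), length(crs_id) == 1)
  if (crs_is_geographic(crs_id))
    stop("geographic (degree-unit) CRS not supported: ", crs_id,
         "; grids must be in a projected metric CRS")
  kind <- match.arg(kind, c("elevation", "canopy_height", "forest_mask",
                            "mixrate", "lambda", "encoded"))
  g <- structure(list(values = values,
                      resolution = as.numeric(resolution),
                      origin = as.numeric(origin),
                      crs_id = crs_id,
                      kind = kind),
                 class = "hemirad_grid")
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  v <- g$values
  if (any(!is.finite(v) & !is.na(v)))
    stop("grid contains non-finite values that are not nodata")
  switch(g$kind,
    canopy_height = if (any(v < 0, na.rm = TRUE))
      stop("canopy heights must be >= 0"),
    forest_mask = if (!all(v[!is.na(v)] %in% c(0, 1, 2)))
      stop("forest mask may only contain codes 0, 1, 2"),
    mixrate = if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("mix-rate fractions must lie in [0, 1]"),
    lambda = if (any(v < 0, na.rm = TRUE))
      stop("lambda values must be >= 0"),
    encoded = if (!all(v[!is.na(v)] == round(v[!is.na(v)])) ||
                  any(v < 0 | v > 100, na.rm = TRUE))
      stop("encoded layers must hold integers in [0, 100]"),
    NULL)
  invisible(g)
}

#' @export
print.hemirad_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hemirad_grid %s> %d x %d cells @ %g m, origin (%g, %g), %s\n",
              x$kind, d[1], d[2], x$resolution, x$origin[1], x$origin[2],
              x$crs_id))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.hemirad_grid <- function(x) dim(x$values)

crs_is_geographic <- function(crs_id) {
  if (grepl("^LOCAL:", crs_id)) return(FALSE)
  if (grepl("^EPSG:", crs_id)) {
    code <- suppressWarnings(as.integer(sub("^EPSG:", "", crs_id)))
    if (!is.na(code))
      return(code == 4326 || code == 4258 || code == 4150 ||
             (code >= 4000 && code < 5000))
  }
  FALSE
}

## Bounding box as c(xmin, xmax, ymin, ymax)
grid_bbox <- function(g) {
  d <- dim(g$values)
  c(g$origin[1], g$origin[1] + d[2] * g$resolution,
    g$origin[2] - d[1] * g$resolution, g$origin[2])
}

grid_contains <- function(g, x, y) {
  b <- grid_bbox(g)
  x >= b[1] & x <= b[2] & y >= b[3] & y <= b[4]
}

## Cell-centre coordinates for row r / column c (vectorised)
grid_cell_xy <- function(g, r, c) {
  list(x = g$origin[1] + (c - 0.5) * g$resolution,
       y = g$origin[2] - (r - 0.5) * g$resolution)
}

## Nearest-cell value lookup at projected coordinates
grid_nearest <- function(g, x, y) {
  d <- dim(g$values)
  c0 <- floor((x - g$origin[1]) / g$resolution) + 1
  r0 <- floor((g$origin[2] - y) / g$resolution) + 1
  ok <- c0 >= 1 & c0 <= d[2] & r0 >= 1 & r0 <= d[1]
  out <- rep(NA_real_, length(x))
  out[ok] <- g$values[cbind(r0[ok], c0[ok])]
  out
}

## Bilinear interpolation between cell centres (constant extrapolation inside
## the outer half-cell margin); NA if outside the grid or any corner is nodata.
grid_bilinear <- function(g, x, y) {
  d <- dim(g$values); ny <- d[1]; nx <- d[2]
  u <- (x - g$origin[1]) / g$resolution - 0.5
  w <- (g$origin[2] - y) / g$resolution - 0.5
  c0 <- floor(u); r0 <- floor(w)
  fu <- u - c0; fw <- w - r0
  inside <- c0 >= -1 & c0 <= nx - 1 & r0 >= -1 & r0 <= ny - 1
  c1 <- pmin(c0 + 1, nx - 1); r1 <- pmin(r0 + 1, ny - 1)
  c0 <- pmax(c0, 0); r0 <- pmax(r0, 0)
  out <- rep(NA_real_, length(x))
  if (any(inside)) {
    i0 <- which(inside)
    z00 <- g$values[cbind(r0[i0] + 1, c0[i0] + 1)]
    z01 <- g$values[cbind(r0[i0] + 1, c1[i0] + 1)]
    z10 <- g$values[cbind(r1[i0] + 1, c0[i0] + 1)]
    z11 <- g$values[cbind(r1[i0] + 1, c1[i0] + 1)]
    top <- z00 + fu[i0] * (z01 - z00)
    bot <- z10 + fu[i0] * (z11 - z10)
    out[i0] <- top + fw[i0] * (bot - top)
  }
  out
}

#' Convert projected grid coordinates to geographic latitude/longitude
#'
#' Supports the Swiss LV95 projection (`EPSG:2056`) through the swisstopo
#' approximate series expansion (accurate to ~1 m over Switzerland) and the
#' `LOCAL:<lat>,<lon>` tangent-plane convention used by synthetic scenes.
#'
#' @param crs_id CRS identifier string of the projected frame.
#' @param x,y Projected coordinates in metres.
#' @return A list with numeric vectors `lat` and `lon` in degrees.
#' @export
projected_to_latlon <- function(crs_id, x, y) {
  if (grepl("^LOCAL:", crs_id)) {
    anchor <- as.numeric(strsplit(sub("^LOCAL:", "", crs_id), ",")[[1]])
    if (length(anchor) != 2 || any(is.na(anchor)))
      stop("malformed LOCAL crs_id: ", crs_id)
    m_per_deg <- pi / 180 * 6371008.8
    lat <- anchor[1] + y / m_per_deg
    lon <- anchor[2] + x / (m_per_deg * cos(anchor[1] * pi / 180))
    return(list(lat = lat, lon = lon))
  }
  if (crs_id == "EPSG:2056" || crs_id == "EPSG:21781") {
    ## swisstopo approximate formulas; LV03 = LV95 - (2e6, 1e6)
    E <- if (crs_id == "EPSG:2056") x - 2600000 else x - 600000
    N <- if (crs_id == "EPSG:2056") y - 1200000 else y - 200000
    yp <- E / 1e6; xp <- N / 1e6
    lonp <- 2.6779094 + 4.728982 * yp + 0.791484 * yp * xp +
      0.1306 * yp * xp^2 - 0.0436 * yp^3
    latp <- 16.9023892 + 3.238272 * xp - 0.270978 * yp^2 -
      0.002528 * xp^2 - 0.0447 * yp^2 * xp - 0.0140 * xp^3
    return(list(lat = latp * 100 / 36, lon = lonp * 100 / 36))
  }
  stop("no inverse projection available for CRS ", crs_id)
}
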