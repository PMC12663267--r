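## Minimal single-band GeoTIFF I/O.
##
## The package writes and reads uncompressed, single-strip, single-band
## GeoTIFFs with ModelPixelScale/ModelTiepoint georeferencing, a
## GeoKeyDirectory (model type + CRS), the GDAL nodata convention and an
## ImageDescription carrying the grid kind. Elevation-like grids are stored
## as 64-bit floats (lossless round trip), masks and 8-bit encoded layers as
## unsigned bytes. This is a deliberately small, self-contained reader for
## the package's own conventions plus plain uncompressed GeoTIFFs from
## elsewhere; tiled or compressed files are rejected with a clear error.

TIFF_TYPE_SIZES <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `12` = 8)

tiff_value_raw <- function(type, values) {
  switch(as.character(type),
    `1` = as.raw(values),
    `2` = c(charToRaw(paste0(values, collapse = "")), as.raw(0)),
    `3` = writeBin(as.integer(values), raw(), size = 2, endian = "little"),
    `4` = writeBin(as.integer(values), raw(), size = 4, endian = "little"),
    `12` = writeBin(as.double(values), raw(), size = 8, endian = "little"),
    stop("unsupported TIFF type ", type))
}

## ---- writer ----------------------------------------------------------------

write_geotiff <- function(values, resolution, origin, crs_id, path,
                          sample = c("float64", "uint8"),
                          nodata = NULL, description = NULL) {
  sample <- match.arg(sample)
  ny <- nrow(values); nx <- ncol(values)
  v <- as.vector(t(values))          # row-major pixel order
  if (!is.null(nodata)) v[is.na(v)] <- nodata
  if (sample == "uint8") {
    if (any(is.na(v)) || any(v < 0 | v > 255))
      stop("uint8 sample values must be integers in [0, 255] after nodata fill")
    pixel_raw <- as.raw(as.integer(round(v)))
    bits <- 8L; fmt <- 1L
  } else {
    pixel_raw <- writeBin(as.double(v), raw(), size = 8, endian = "little")
    bits <- 64L; fmt <- 3L
  }

  ## GeoKeyDirectory: projected model, citation string carries the crs_id
  citation <- paste0(crs_id, "|")
  epsg <- if (grepl("^EPSG:", crs_id))
    suppressWarnings(as.integer(sub("^EPSG:", "", crs_id))) else NA_integer_
  geokeys <- c(1, 1, 0, 3,
               1024, 0, 1, 1,                       # GTModelType = projected
               1026, 34737, nchar(citation), 0,     # GTCitation in ascii params
               3072, 0, 1, if (is.na(epsg)) 32767 else epsg)

  tags <- list(
    list(code = 256L, type = 4L, values = nx),
    list(code = 257L, type = 4L, values = ny),
    list(code = 258L, type = 3L, values = bits),
    list(code = 259L, type = 3L, values = 1L),
    list(code = 262L, type = 3L, values = 1L),
    if (!is.null(description))
      list(code = 270L, type = 2L, values = description),
    list(code = 273L, type = 4L, values = NA),   # StripOffsets, patched below
    list(code = 277L, type = 3L, values = 1L),
    list(code = 278L, type = 4L, values = ny),
    list(code = 279L, type = 4L, values = length(pixel_raw)),
    list(code = 284L, type = 3L, values = 1L),
    list(code = 339L, type = 3L, values = fmt),
    list(code = 33550L, type = 12L, values = c(resolution, resolution, 0)),
    list(code = 33922L, type = 12L, values = c(0, 0, 0, origin[1], origin[2], 0)),
    list(code = 34735L, type = 3L, values = geokeys),
    list(code = 34737L, type = 2L, values = citation),
    if (!is.null(nodata))
      list(code = 42113L, type = 2L, values = format(nodata, scientific = FALSE)))
  tags <- Filter(Negate(is.null), tags)

  n <- length(tags)
  ifd_end <- 8L + 2L + 12L * n + 4L
  ## lay out external value blocks, then pixel data
  ext_off <- ifd_end
  for (i in seq_along(tags)) {
    t <- tags[[i]]
    if (t$code == 273L) { tags[[i]]$raw <- raw(0); next }
    r <- tiff_value_raw(t$type, t$values)
    tags[[i]]$count <- if (t$type == 2L) length(r) else length(t$values)
    tags[[i]]$raw <- r
    if (length(r) > 4L) {
      if (ext_off %% 2L == 1L) ext_off <- ext_off + 1L
      tags[[i]]$offset <- ext_off
      ext_off <- ext_off + length(r)
    }
  }
  data_off <- ext_off + (ext_off %% 2L)
  for (i in seq_along(tags))
    if (tags[[i]]$code == 273L) {
      tags[[i]]$count <- 1L
      tags[[i]]$raw <- tiff_value_raw(4L, data_off)
    }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(as.integer(n), con, size = 2, endian = "little")
  for (t in tags) {
    writeBin(as.integer(t$code), con, size = 2, endian = "little")
    writeBin(as.integer(t$type), con, size = 2, endian = "little")
    writeBin(as.integer(t$count), con, size = 4, endian = "little")
    if (length(t$raw) > 4L) {
      writeBin(as.integer(t$offset), con, size = 4, endian = "little")
    } else {
      pad <- c(t$raw, raw(4L - length(t$raw)))
      writeBin(pad, con)
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  pos <- ifd_end
  for (t in tags)
    if (length(t$raw) > 4L) {
      if (pos < t$offset) { writeBin(raw(t$offset - pos), con); pos <- t$offset }
      writeBin(t$raw, con)
      pos <- pos + length(t$raw)
    }
  if (pos < data_off) writeBin(raw(data_off - pos), con)
  writeBin(pixel_raw, con)
  invisible(path)
}

## ---- reader ----------------------------------------------------------------

read_geotiff <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file: ", path)
  bom <- rawToChar(raw_all[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big" else
    stop("not a TIFF file: ", path)
  rd_int <- function(off, size, n = 1L)
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4)   # sizes 1-2 read unsigned
  rd_dbl <- function(off, n = 1L)
    readBin(raw_all[(off + 1):(off + 8 * n)], "double", n = n, size = 8,
            endian = endian)
  if (rd_int(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- rd_int(4, 4)
  ntag <- rd_int(ifd, 2)
  tags <- list()
  for (i in seq_len(ntag)) {
    base <- ifd + 2 + (i - 1) * 12
    code <- rd_int(base, 2)
    type <- rd_int(base + 2, 2)
    count <- rd_int(base + 4, 4)
    sz <- TIFF_TYPE_SIZES[as.character(type)]
    if (is.na(sz)) next
    nbytes <- sz * count
    off <- if (nbytes > 4) rd_int(base + 8, 4) else base + 8
    vals <- switch(as.character(type),
      `1` = as.integer(raw_all[(off + 1):(off + count)]),
      `2` = {
        bb <- raw_all[(off + 1):(off + count)]
        rawToChar(bb[bb != as.raw(0)])
      },
      `3` = rd_int(off, 2, count),
      `4` = rd_int(off, 4, count),
      `12` = rd_dbl(off, count))
    tags[[as.character(code)]] <- vals
  }
  tg <- function(code, default = NULL)
    if (!is.null(tags[[as.character(code)]])) tags[[as.character(code)]] else default

  if (tg(259, 1L) != 1L) stop("only uncompressed TIFFs are supported: ", path)
  if (!is.null(tg(322))) stop("tiled TIFFs are not supported: ", path)
  nx <- tg(256); ny <- tg(257)
  bits <- tg(258, 8L); fmt <- tg(339, 1L)
  strip_off <- tg(273); strip_cnt <- tg(279)
  if (is.null(nx) || is.null(ny) || is.null(strip_off))
    stop("malformed TIFF: ", path)
  data_raw <- do.call(c, lapply(seq_along(strip_off), function(i)
    raw_all[(strip_off[i] + 1):(strip_off[i] + strip_cnt[i])]))
  npx <- nx * ny
  v <- if (fmt == 3L && bits == 64L) {
    readBin(data_raw, "double", n = npx, size = 8, endian = endian)
  } else if (fmt == 3L && bits == 32L) {
    readBin(data_raw, "double", n = npx, size = 4, endian = endian)
  } else if (bits == 8L) {
    as.numeric(as.integer(data_raw[seq_len(npx)]))
  } else if (bits == 16L) {
    as.numeric(readBin(data_raw, "integer", n = npx, size = 2, endian = endian,
                       signed = fmt == 2L))
  } else if (bits == 32L) {
    as.numeric(readBin(data_raw, "integer", n = npx, size = 4, endian = endian))
  } else stop("unsupported sample layout (bits=", bits, ", format=", fmt, ")")
  values <- matrix(v, nrow = ny, byrow = TRUE)

  scale <- tg(33550)
  tie <- tg(33922)
  if (is.null(scale) || is.null(tie))
    stop("TIFF lacks georeferencing (ModelPixelScale/ModelTiepoint): ", path)
  resolution <- scale[1]
  origin <- c(tie[4] - tie[1] * scale[1], tie[5] + tie[2] * scale[2])

  geokeys <- tg(34735)
  ascii <- tg(34737, "")
  model_type <- NA_integer_; epsg <- NA_integer_; citation <- NULL
  if (!is.null(geokeys) && length(geokeys) >= 4) {
    nk <- geokeys[4]
    for (k in seq_len(nk)) {
      key <- geokeys[4 * k + 1:4]
      if (key[1] == 1024) model_type <- key[4]
      if (key[1] %in% c(3072, 2048)) epsg <- key[4]
      if (key[1] == 1026 && key[2] == 34737)
        citation <- substr(ascii, key[4] + 1, key[4] + key[3])
    }
  }
  if (identical(model_type, 2L) || identical(model_type, 2))
    stop("geographic (degree-unit) CRS not supported: ", path)
  crs_id <- if (!is.null(citation) && nzchar(citation)) {
    sub("\\|$", "", citation)
  } else if (!is.na(epsg) && epsg != 32767) {
    paste0("EPSG:", epsg)
  } else "UNKNOWN"

  nodata <- tg(42113)
  if (!is.null(nodata)) {
    nd <- suppressWarnings(as.numeric(nodata))
    if (!is.na(nd)) values[values == nd] <- NA
  }
  values[is.nan(values)] <- NA

  list(values = values, resolution = resolution, origin = origin,
       crs_id = crs_id, description = tg(270))
}

## ---- public surface --------------------------------------------------------

#' Read a georeferenced raster as a typed grid
#'
#' Reads a single-band uncompressed GeoTIFF and returns a [raster_grid()] of
#' the requested kind, with nodata mapped to `NA`. Files in a geographic
#' (degree-unit) CRS are rejected, as are forest masks containing codes
#' outside \{0, 1, 2\}.
#'
#' @param path Path to a GeoTIFF file.
#' @param expected_kind Grid kind to validate against: `"elevation"`,
#'   `"canopy_height"`, `"forest_mask"`, `"mixrate"`, `"lambda"` or
#'   `"encoded"`. If the file carries a kind in its description, the two must
#'   agree.
#' @return A `hemirad_grid`.
#' @seealso [write_grid()]
#' @export
read_grid <- function(path, expected_kind = "elevation") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_geotiff(path)
  kind <- expected_kind
  if (!is.null(raw$description) && grepl("kind=", raw$description)) {
    stored <- sub(".*kind=([a-z_]+).*", "\\1", raw$description)
    if (!identical(stored, expected_kind))
      stop("file declares kind '", stored, "' but '", expected_kind,
           "' was expected: ", path)
  }
  g <- raster_grid(raw$values, raw$resolution, raw$origin, raw$crs_id,
                   kind = kind)
  if (!is.null(raw$description)) attr(g, "description") <- raw$description
  g
}

#' Write a grid as a single-band GeoTIFF
#'
#' Elevation-like grids (elevation, canopy height, mix rate, lambda) are
#' stored as 64-bit floats so that a write/read round trip is exact; forest
#' masks and 8-bit encoded layers are stored as unsigned bytes with nodata
#' sentinel 255.
#'
#' @param grid A `hemirad_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "hemirad_grid"))
  desc <- attr(grid, "description")
  if (is.null(desc)) desc <- paste0("kind=", grid$kind)
  if (grid$kind %in% c("forest_mask", "encoded")) {
    write_geotiff(grid$values, grid$resolution, grid$origin, grid$crs_id,
                  path, sample = "uint8", nodata = 255, description = desc)
  } else {
    write_geotiff(grid$values, grid$resolution, grid$origin, grid$crs_id,
                  path, sample = "float64", nodata = -9999,
                  description = desc)
  }
  invisible(path)
}
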