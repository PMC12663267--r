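#' Per-pixel effective foliage density (lambda) grids
#'
#' Builds a 1 m lambda grid for one leaf condition from the 10 m
#' evergreen/deciduous mix-rate raster: the mix rate is first replicated to
#' the CHM resolution by nearest neighbour, then lambda is interpolated
#' linearly between the forest-type endpoints, `lambda = f * lambda_evergreen
#' + (1 - f) * lambda_deciduous`, where `f` is the evergreen fraction. The
#' deciduous endpoint depends on the regional forest class: broadleaf
#' regions use the broadleaf deciduous lambda, needleleaf regions use the
#' larch lambda. Cells flagged `forced_larch` are treated as pure larch
#' forest (the interpolation is overridden entirely).
#'
#' @param mix A mix-rate `hemirad_grid` (fraction evergreen, 10 m nominal).
#' @param condition `"leaf_on"` or `"leaf_off"`.
#' @param config A [model_config()] supplying the lambda endpoints.
#' @param forest_class Integer `hemirad_grid` co-located with `mix` (any
#'   kind; values 1 = broadleaf region, 2 = needleleaf region, 3 =
#'   forced larch), or a single value applied everywhere. Defaults to
#'   broadleaf region.
#' @param target Grid whose geometry the lambda grid should take (normally
#'   the CHM); defaults to the mix grid itself.
#' @return A lambda `hemirad_grid` with attribute `leaf_condition`.
#' @examples
#' mix <- raster_grid(matrix(0.25, 2, 2), 10, c(0, 20), kind = "mixrate")
#' cfg <- model_config(lambda_evergreen = 1, lambda_deciduous_on = 0.2)
#' interpolate_lambda(mix, "leaf_on", cfg)$values[1, 1]  # 0.4
#' @export
interpolate_lambda <- function(mix, condition = c("leaf_on", "leaf_off"),
                               config = model_config(), forest_class = 1L,
                               target = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(mix, "hemirad_grid"), mix$kind == "mixrate")
  if (is.null(target)) target <- mix
  d <- dim(target$values)
  xy <- grid_cell_xy(target, row(target$values), col(target$values))
  f <- grid_nearest(mix, as.vector(xy$x), as.vector(xy$y))
  cls <- if (inherits(forest_class, "hemirad_grid")) {
    grid_nearest(forest_class, as.vector(xy$x), as.vector(xy$y))
  } else rep(as.numeric(forest_class), length(f))
  cls[is.na(cls)] <- 1

  lam_ev <- config$lambda_evergreen
  lam_dec <- ifelse(cls == 2,
                    if (condition == "leaf_on") config$lambda_larch_on
                    else config$lambda_larch_off,
                    if (condition == "leaf_on") config$lambda_deciduous_on
                    else config$lambda_deciduous_off)
  lam <- f * lam_ev + (1 - f) * lam_dec
  forced <- cls == 3
  lam[forced] <- if (condition == "leaf_on") config$lambda_larch_on
                 else config$lambda_larch_off
  g <- raster_grid(matrix(lam, d[1], d[2]), target$resolution, target$origin,
                   target$crs_id, kind = "lambda")
  attr(g, "leaf_condition") <- condition
  g
}

#' Larch override flags
#'
#' Alpine larch stands are systematically mislabelled by the standard
#' products: the ecoregion says needleleaf, the dominant-leaf-type product
#' says broadleaf, and the mix rate calls the pixel evergreen-majority. Where
#' all three disagree in exactly that way *and* the pixel lies above 1500 m
#' a.s.l., the model is forced to assume a larch forest. The elevation gate
#' keeps lowland product disagreements from being mislabelled as larch.
#'
#' @param mix A mix-rate `hemirad_grid` (fraction evergreen).
#' @param ecoregion_is_needleleaf,dlt_is_broadleaf Logical matrices (or
#'   `hemirad_grid`s co-registered with `mix`) of per-cell flags.
#' @param elevation An elevation `hemirad_grid` (sampled bilinearly at the
#'   mix grid's cell centres).
#' @return A logical matrix of `forced_larch` flags, same shape as `mix`.
#' @export
larch_override <- function(mix, ecoregion_is_needleleaf, dlt_is_broadleaf,
                           elevation) {
  stopifnot(inherits(mix, "hemirad_grid"))
  as_mat <- function(x) {
    if (inherits(x, "hemirad_grid")) x <- x$values
    x <- as.matrix(x)
    if (!all(dim(x) == dim(mix$values)))
      stop("flag layers must be co-registered with the mix-rate grid")
    x
  }
  eco <- as_mat(ecoregion_is_needleleaf) > 0
  dlt <- as_mat(dlt_is_broadleaf) > 0
  xy <- grid_cell_xy(mix, row(mix$values), col(mix$values))
  elev <- matrix(grid_bilinear(elevation, as.vector(xy$x), as.vector(xy$y)),
                 nrow(mix$values), ncol(mix$values))
  flags <- (elev > 1500) & eco & dlt & (mix$values > 0.5)
  flags[is.na(flags)] <- FALSE
  flags
}
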