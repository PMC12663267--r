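#' Reconstruct surface shortwave radiation from DBT and SVF
#'
#' Combines above-canopy shortwave forcing, split into direct and diffuse
#' components, with the point's direct-beam transmissivity series and
#' sky-view factor: `SWR_i = SWR_dir,i * DBT_i + SWR_dif,i * SVF`. Which SVF
#' variant to use (planar for flat ground/snow surfaces, hemispheric for
#' 3-D receivers such as plants) is the caller's choice.
#'
#' @param swr_dir,swr_dif Non-negative numeric vectors (W m^-2), aligned in
#'   time with `dbt`.
#' @param dbt DBT fractions in `[0, 1]`, same length as the forcing.
#' @param svf A single sky-view-factor fraction in `[0, 1]`.
#' @return Numeric vector of surface shortwave radiation (W m^-2).
#' @examples
#' surface_swr(swr_dir = 600, swr_dif = 100, dbt = 0, svf = 0.5)  # 50
#' @export
surface_swr <- function(swr_dir, swr_dif, dbt, svf) {
  if (length(swr_dir) != length(swr_dif) || length(swr_dir) != length(dbt))
    stop("forcing and DBT series are not aligned (different lengths)")
  stopifnot(length(svf) == 1, svf >= 0, svf <= 1)
  if (any(swr_dir < 0 | swr_dif < 0, na.rm = TRUE))
    stop("forcing components must be >= 0")
  if (any(dbt < 0 | dbt > 1, na.rm = TRUE))
    stop("DBT values must lie in [0, 1]")
  swr_dir * dbt + swr_dif * svf
}

#' Maximum potential shortwave radiation
#'
#' Clear-sky upper bound `I0 * cos(zenith) * tau_atm` with the solar
#' constant `I0 = 1361` W m^-2, clamped to 0 when the sun is at or below the
#' astronomical horizon. With `tau_atm = 1` this is the extraterrestrial
#' flux on a horizontal surface; multiply by DBT/SVF via [surface_swr()]
#' when no measured forcing is available.
#'
#' @param zenith Solar zenith angle(s) in degrees.
#' @param tau_atm Atmospheric transmissivity in `(0, 1]`.
#' @return Numeric vector (W m^-2).
#' @examples
#' max_potential_swr(0, 1)    # 1361
#' max_potential_swr(60, 1)   # 680.5
#' @export
max_potential_swr <- function(zenith, tau_atm = 1) {
  stopifnot(tau_atm > 0, tau_atm <= 1)
  I0 <- 1361
  pmax(cos(zenith * pi / 180), 0) * I0 * tau_atm * (zenith < 90)
}
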