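#' Net surface heat flux
#'
#' Sum of the shortwave, longwave, latent and sensible components,
#' positive towards the ocean. Any missing component masks the result.
#'
#' @param sw,lw,latent,sensible component fluxes, W m-2 (vectors or
#'   arrays of equal shape).
#' @return Net heat flux, W m-2.
#' @examples
#' net_heat_flux(170, -80, -70, -30)  # -10
#' @export
net_heat_flux <- function(sw, lw, latent, sensible) {
  sw + lw + latent + sensible
}

#' Wind stress from 10-m wind components
#'
#' Bulk formula `tau = rho_air * c_d * (u10^2 + v10^2)`.
#'
#' @param u10,v10 10-m wind components, m s-1.
#' @param rho_air air density, kg m-3.
#' @param c_d drag coefficient.
#' @return Wind stress magnitude, N m-2.
#' @examples
#' wind_stress(10, 0)  # 0.1586
#' @export
wind_stress <- function(u10, v10, rho_air = 1.22, c_d = 1.3e-3) {
  rho_air * c_d * (u10^2 + v10^2)
}

#' Net specific growth rate of surface chlorophyll
#'
#' Logarithmic derivative over consecutive 8-day windows:
#' `r_t = (ln SChl_{t+1} - ln SChl_t) / 8` in day-1, assigned to the
#' interval starting at window `t` (length `n - 1`). Intervals touching a
#' masked value are `NA`.
#'
#' @param schl surface chlorophyll series, mg Chl m-3 (positive where
#'   unmasked).
#' @param step_days window length in days.
#' @return Numeric vector of length `length(schl) - 1`, day-1.
#' @export
net_growth_rate <- function(schl, step_days = 8) {
  bad <- which(!is.na(schl) & schl <= 0)
  if (length(bad))
    stop("SChl must be positive where unmasked; first offending step: ",
         bad[1])
  diff(log(schl)) / step_days
}

#' Forward difference quotient of a series
#'
#' `(x_{t+1} - x_t) / step_days`, assigned to the interval starting at
#' window `t`.
#'
#' @param x numeric series (NA = masked).
#' @param step_days window length in days.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
forward_derivative <- function(x, step_days = 8) {
  diff(x) / step_days
}

#' Season membership of windows or derivative intervals
#'
#' Winter is January-February, spring March-April, by calendar month of
#' the window center. With `intervals = TRUE` the mask refers to the
#' `n - 1` forward-derivative intervals, each assigned to the season of
#' its first window.
#'
#' @param axis a `time_axis`.
#' @param season `"winter"` or `"spring"`.
#' @param intervals logical; label intervals instead of windows.
#' @return Logical vector.
#' @export
season_mask <- function(axis, season = c("winter", "spring"),
                        intervals = FALSE) {
  season <- match.arg(season)
  months <- if (season == "winter") 1:2 else 3:4
  m <- axis_month(axis) %in% months
  if (intervals) m[-length(m)] else m
}
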