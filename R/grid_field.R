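#' Gridded time-varying field
#'
#' Container for a single variable on a regular latitude-longitude grid and
#' a shared time axis. Missing values are `NA` in `values`.
#'
#' @param name variable name (e.g. `"schl"`).
#' @param units unit string (must be non-empty).
#' @param lat,lon coordinate vectors of pixel centers, strictly increasing
#'   with regular spacing.
#' @param axis a [time_axis_8day()]-style `time_axis`.
#' @param values numeric array with dim `c(axis$n_steps, length(lat),
#'   length(lon))`.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(name, units, lat, lon, axis, values) {
  stopifnot(is.character(name), nzchar(units))
  check_regular <- function(v, what) {
    if (length(v) > 1) {
      dv <- diff(v)
      if (any(dv <= 0)) stop(what, " coordinates must be strictly increasing")
      if (max(dv) - min(dv) > 1e-6 * max(abs(dv)))
        stop(what, " coordinates must be regularly spaced")
    }
  }
  check_regular(lat, "lat"); check_regular(lon, "lon")
  values <- array(as.numeric(values),
                  dim = c(axis$n_steps, length(lat), length(lon)))
  structure(list(name = name, units = units, lat = as.numeric(lat),
                 lon = as.numeric(lon), axis = axis, values = values),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s], %d x %d pixels, %d steps\n",
              x$name, x$units, length(x$lat), length(x$lon), x$axis$n_steps))
  invisible(x)
}

#' Co-registered surface-chlorophyll and forcing fields
#'
#' Bundles SChl (mg Chl m-3), net heat flux (W m-2, positive = ocean heat
#' gain) and wind stress (N m-2) on one grid and one 8-day time axis: the
#' universal input of the analysis chain.
#'
#' @param schl,nhf,ws `grid_field`s on identical axes and grids.
#' @return An object of class `forcing_bundle`.
#' @export
forcing_bundle <- function(schl, nhf, ws) {
  flds <- list(schl = schl, nhf = nhf, ws = ws)
  for (nm in names(flds)) {
    f <- flds[[nm]]
    if (!inherits(f, "grid_field")) stop("'", nm, "' must be a grid_field")
    if (!same_axis(f$axis, schl$axis) ||
        !isTRUE(all.equal(f$lat, schl$lat)) ||
        !isTRUE(all.equal(f$lon, schl$lon)))
      stop("field '", nm, "' is not on the same grid/axis as 'schl'")
  }
  if (any(schl$values <= 0, na.rm = TRUE))
    stop("SChl must be strictly positive where unmasked")
  structure(flds, class = "forcing_bundle")
}

#' @export
print.forcing_bundle <- function(x, ...) {
  cat(sprintf("<forcing_bundle> %d x %d pixels, %d steps (%s .. %s)\n",
              length(x$schl$lat), length(x$schl$lon), x$schl$axis$n_steps,
              format(x$schl$axis$center[1]),
              format(x$schl$axis$center[x$schl$axis$n_steps])))
  invisible(x)
}

#' Extract one pixel of a bundle as a data frame
#'
#' @param bundle a `forcing_bundle`.
#' @param i_lat,i_lon pixel indices.
#' @return A data frame with columns `date` (window center), `schl`,
#'   `nhf`, `ws`.
#' @export
bundle_pixel <- function(bundle, i_lat = 1L, i_lon = 1L) {
  data.frame(date = bundle$schl$axis$center,
             schl = bundle$schl$values[, i_lat, i_lon],
             nhf = bundle$nhf$values[, i_lat, i_lon],
             ws = bundle$ws$values[, i_lat, i_lon])
}
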