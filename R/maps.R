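#' Per-pixel seasonal climatology
#'
#' Mean over all steps of the chosen season across all years. Pixels with
#' no valid in-season step are masked.
#'
#' @param field a `grid_field`.
#' @param season `"winter"` (Jan-Feb) or `"spring"` (Mar-Apr).
#' @return A single-time-step `grid_field` of seasonal means.
#' @export
seasonal_climatology <- function(field, season = c("winter", "spring")) {
  season <- match.arg(season)
  sel <- season_mask(field$axis, season)
  if (!any(sel)) stop("no ", season, " steps in the series")
  dm <- dim(field$values)
  out <- array(NA_real_, c(1, dm[2], dm[3]))
  for (i in seq_len(dm[2])) {
    for (j in seq_len(dm[3])) {
      v <- field$values[sel, i, j]
      if (any(!is.na(v))) out[1, i, j] <- mean(v, na.rm = TRUE)
    }
  }
  grid_field(paste0(field$name, "_clim_", season), field$units,
             field$lat, field$lon, single_step_axis(field$axis), out)
}

single_step_axis <- function(axis) {
  new_time_axis(axis$start[1], axis$center[1], axis$end[1],
                axis$year[1], axis$step[1], axis$step_days)
}

#' Bloom-region mask
#'
#' Pixels whose climatological spring SChl strictly exceeds the
#' threshold. Masked climatology pixels are `FALSE`.
#'
#' @param spring_clim spring climatology `grid_field`, mg Chl m-3.
#' @param threshold mg Chl m-3 (default 0.65).
#' @return A logical matrix (`n_lat x n_lon`).
#' @export
bloom_mask <- function(spring_clim, threshold = 0.65) {
  if (threshold < 0) stop("threshold must be non-negative")
  v <- spring_clim$values[1, , , drop = TRUE]
  m <- matrix(v, length(spring_clim$lat), length(spring_clim$lon))
  mask <- !is.na(m) & m > threshold
  dimnames(mask) <- NULL
  mask
}

#' Sign-agreement percentage map
#'
#' Per pixel, 100 times the fraction of in-season growth intervals where
#' the driver derivative and the net growth rate have the same sign,
#' counted over intervals where both are nonzero and unmasked. For the
#' wind-stress driver agreement means opposite signs (a wind-stress drop
#' goes with a chlorophyll rise). Pixels with fewer than `min_count`
#' countable intervals are masked.
#'
#' @param growth array `(n_steps - 1, n_lat, n_lon)` of net growth rates,
#'   day-1.
#' @param driver array of the same shape: the driver derivative per
#'   interval.
#' @param axis the `time_axis` of the underlying (step) series.
#' @param season `"winter"` or `"spring"`.
#' @param driver_name `"nhf"` (same sign counts) or `"ws"` (opposite
#'   sign counts).
#' @param lat,lon grid coordinates.
#' @param min_count minimum countable intervals per pixel.
#' @return A single-time-step `grid_field` of percentages.
#' @export
sign_agreement_map <- function(growth, driver, axis,
                               season = c("winter", "spring"),
                               driver_name = c("nhf", "ws"),
                               lat, lon, min_count = 5) {
  season <- match.arg(season)
  driver_name <- match.arg(driver_name)
  sel <- season_mask(axis, season, intervals = TRUE)
  flip <- if (driver_name == "ws") -1 else 1
  dm <- dim(growth)
  stopifnot(all(dim(driver) == dm), dm[1] == axis$n_steps - 1)
  out <- array(NA_real_, c(1, dm[2], dm[3]))
  for (i in seq_len(dm[2])) {
    for (j in seq_len(dm[3])) {
      g <- growth[sel, i, j]
      d <- flip * driver[sel, i, j]
      ok <- !is.na(g) & !is.na(d) & g != 0 & d != 0
      if (sum(ok) < min_count) next
      out[1, i, j] <- 100 * mean(sign(g[ok]) == sign(d[ok]))
    }
  }
  grid_field(paste0("sign_agreement_", driver_name, "_", season), "%",
             lat, lon, single_step_axis(axis), out)
}

#' Write a boolean mask as an ASCII 0/1 grid
#'
#' Plain-text export: a header with the grid coordinates followed by one
#' row of 0/1 per latitude (southernmost first), space-separated.
#'
#' @param mask logical matrix (`n_lat x n_lon`).
#' @param lat,lon grid coordinates.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_ascii <- function(mask, lat, lon, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("nlat %d", length(lat)),
               sprintf("nlon %d", length(lon)),
               paste("lat", paste(format(lat, trim = TRUE), collapse = " ")),
               paste("lon", paste(format(lon, trim = TRUE), collapse = " "))),
             con)
  for (i in seq_along(lat))
    writeLines(paste(as.integer(mask[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ASCII 0/1 mask written by [write_mask_ascii()]
#'
#' @param path file path.
#' @return A list with `mask` (logical matrix), `lat`, `lon`.
#' @export
read_mask_ascii <- function(path) {
  lines <- readLines(path)
  nlat <- as.integer(strsplit(lines[1], " ")[[1]][2])
  nlon <- as.integer(strsplit(lines[2], " ")[[1]][2])
  lat <- as.numeric(strsplit(lines[3], " ")[[1]][-1])
  lon <- as.numeric(strsplit(lines[4], " ")[[1]][-1])
  rows <- lapply(lines[4 + seq_len(nlat)],
                 function(l) as.integer(strsplit(l, " ")[[1]]))
  mask <- do.call(rbind, rows) == 1L
  stopifnot(ncol(mask) == nlon)
  list(mask = mask, lat = lat, lon = lon)
}
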