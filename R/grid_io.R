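#' Aggregate a series onto the 8-day compositing axis
#'
#' Each output step is the arithmetic mean of the source values whose
#' window centers fall in `[center - 4d, center + 4d)` of that step.
#' Output steps covering fewer than 4 valid source days are masked, so a
#' daily window needs at least 4 good days while aggregating an existing
#' 8-day series onto its own axis is the identity.
#'
#' @param field a `grid_field` (typically on a daily axis).
#' @param target the target 8-day `time_axis`.
#' @return A `grid_field` on `target`.
#' @export
aggregate_time_8day <- function(field, target) {
  src <- field$axis
  if (max(src$center) < min(target$start) ||
      min(src$center) > max(target$end))
    stop("source series does not overlap the target axis")
  half <- 4L
  dm <- dim(field$values)
  out <- array(NA_real_, c(target$n_steps, dm[2], dm[3]))
  for (t in seq_len(target$n_steps)) {
    sel <- which(src$center >= target$center[t] - half &
                   src$center < target$center[t] + half)
    if (!length(sel)) next
    for (i in seq_len(dm[2])) {
      for (j in seq_len(dm[3])) {
        v <- field$values[sel, i, j]
        ok <- !is.na(v)
        if (sum(ok) * src$step_days >= 4)
          out[t, i, j] <- mean(v[ok])
      }
    }
  }
  grid_field(field$name, field$units, field$lat, field$lon, target, out)
}

#' Bilinear regridding of a field
#'
#' Interpolates each time step onto a new regular grid with bilinear
#' weights. A target point whose 4-cell stencil contains any masked
#' source cell is masked. Target coordinates are clamped to the source
#' bounding box, so points on (or marginally beyond) the edge take the
#' nearest edge value.
#'
#' @param field a `grid_field` with at least 2 points per axis.
#' @param target_lat,target_lon target coordinate vectors (regular,
#'   increasing).
#' @return A `grid_field` on the target grid.
#' @export
regrid_bilinear <- function(field, target_lat, target_lon) {
  if (length(field$lat) < 2 || length(field$lon) < 2)
    stop("source grid needs at least 2 points per axis")
  qlat <- pmin(pmax(target_lat, min(field$lat)), max(field$lat))
  qlon <- pmin(pmax(target_lon, min(field$lon)), max(field$lon))
  pts <- expand.grid(lat = qlat, lon = qlon)
  n <- field$axis$n_steps
  out <- array(NA_real_, c(n, length(target_lat), length(target_lon)))
  for (t in seq_len(n)) {
    z <- matrix(field$values[t, , ], length(field$lat), length(field$lon))
    vals <- pracma::interp2(x = field$lon, y = field$lat, Z = z,
                            xp = pts$lon, yp = pts$lat, method = "linear")
    out[t, , ] <- matrix(vals, length(target_lat), length(target_lon))
  }
  grid_field(field$name, field$units, target_lat, target_lon,
             field$axis, out)
}

#' Box-mean pixel series
#'
#' Unweighted mean over the unmasked pixels whose centers fall inside
#' the closed lat/lon box, per time step.
#'
#' @param field a `grid_field`.
#' @param lat_range,lon_range numeric length-2 bounds (closed on pixel
#'   centers).
#' @return Numeric series of length `axis$n_steps`.
#' @export
extract_box_mean <- function(field, lat_range, lon_range) {
  ii <- which(field$lat >= min(lat_range) & field$lat <= max(lat_range))
  jj <- which(field$lon >= min(lon_range) & field$lon <= max(lon_range))
  if (!length(ii) || !length(jj))
    stop("box contains no grid pixels")
  sub <- field$values[, ii, jj, drop = FALSE]
  apply(sub, 1, function(m) {
    if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
  })
}

nc_units <- list(schl = "mg m-3", nhf = "W m-2", ws = "N m-2")
nc_longname <- list(schl = "surface chlorophyll concentration",
                    nhf = "net air-sea heat flux, positive downward",
                    ws = "surface wind stress magnitude")

#' Write a forcing bundle to NetCDF
#'
#' Dimensions `(time, lat, lon)`; variables `schl`, `nhf`, `ws` with
#' `units` and `long_name` attributes, plus `time` (window center) and
#' `time_start` in days since 1970-01-01.
#'
#' @param bundle a `forcing_bundle`.
#' @param path output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  ax <- bundle$schl$axis
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", bundle$schl$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", bundle$schl$lat)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(ax$center), unlim = TRUE)
  fill <- 1e30
  vars <- lapply(names(nc_units), function(nm)
    ncdf4::ncvar_def(nm, nc_units[[nm]],
                     list(dim_lon, dim_lat, dim_time), fill,
                     longname = nc_longname[[nm]], prec = "double"))
  v_start <- ncdf4::ncvar_def("time_start", "days since 1970-01-01",
                              list(dim_time), fill,
                              longname = "window start date",
                              prec = "double")
  v_end <- ncdf4::ncvar_def("time_end", "days since 1970-01-01",
                            list(dim_time), fill,
                            longname = "window end date (exclusive)",
                            prec = "double")
  nc <- ncdf4::nc_create(path, c(vars, list(v_start, v_end)))
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(vars)) {
    nm <- names(nc_units)[k]
    ncdf4::ncvar_put(nc, vars[[k]], aperm(bundle[[nm]]$values, c(3, 2, 1)))
  }
  ncdf4::ncvar_put(nc, v_start, as.numeric(ax$start))
  ncdf4::ncvar_put(nc, v_end, as.numeric(ax$end))
  invisible(path)
}

#' Read a forcing bundle from NetCDF
#'
#' Inverse of [write_bundle()]; round-trips values, mask, units and time
#' axis.
#'
#' @param path `.nc` path.
#' @return A `forcing_bundle`.
#' @export
read_bundle <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  need <- c("schl", "nhf", "ws", "time_start", "time_end")
  missing_vars <- setdiff(need, names(nc$var))
  if (length(missing_vars))
    stop("file is missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  lat <- ncdf4::ncvar_get(nc, "lat")
  lon <- ncdf4::ncvar_get(nc, "lon")
  start <- as.Date(as.vector(ncdf4::ncvar_get(nc, "time_start")),
                   origin = "1970-01-01")
  end <- as.Date(as.vector(ncdf4::ncvar_get(nc, "time_end")),
                 origin = "1970-01-01")
  axis <- time_axis_from_dates(start, end)
  get_field <- function(nm) {
    v <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    units <- ncdf4::ncatt_get(nc, nm, "units")$value
    grid_field(nm, units, lat, lon, axis, aperm(v, c(3, 2, 1)))
  }
  forcing_bundle(get_field("schl"), get_field("nhf"), get_field("ws"))
}

#' Write a single-pixel series as CSV
#'
#' Comma-separated with a header and ISO-8601 dates: columns
#' `date_start`, `date` (window center), `date_end`, `schl`, `nhf`, `ws`.
#'
#' @param bundle a `forcing_bundle`.
#' @param path output `.csv` path.
#' @param i_lat,i_lon pixel indices.
#' @return `path`, invisibly.
#' @export
write_pixel_csv <- function(bundle, path, i_lat = 1L, i_lon = 1L) {
  ax <- bundle$schl$axis
  df <- data.frame(date_start = format(ax$start),
                   date = format(ax$center),
                   date_end = format(ax$end))
  px <- bundle_pixel(bundle, i_lat, i_lon)
  df$schl <- px$schl; df$nhf <- px$nhf; df$ws <- px$ws
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-pixel CSV series
#'
#' @param path `.csv` written by [write_pixel_csv()] (or matching its
#'   dialect).
#' @return A list with `axis` (a `time_axis`) and the data frame `data`
#'   (`date`, `schl`, `nhf`, `ws`).
#' @export
read_pixel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date_start", "date_end", "schl", "nhf", "ws")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  axis <- time_axis_from_dates(as.Date(df$date_start),
                               as.Date(df$date_end))
  list(axis = axis,
       data = data.frame(date = axis$center, schl = df$schl,
                         nhf = df$nhf, ws = df$ws))
}
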