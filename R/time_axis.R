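#' 8-day composite time axis
#'
#' Builds the standard ocean-colour compositing calendar: windows of 8 days
#' anchored to January 1 of each year (46 windows per year), with the final
#' window of each year truncated at December 31. Window centers are the
#' window start plus half the window length (4 days for full windows).
#'
#' @param start_year first calendar year covered.
#' @param n_years number of years.
#' @param steps_per_year composite windows per year (default 46).
#' @return An object of class `time_axis`: a list with `Date` vectors
#'   `start`, `center`, `end` (exclusive), integer vectors `year` and
#'   `step` (window index within the year), and scalars `n_steps` and
#'   `step_days`.
#' @examples
#' ax <- time_axis_8day(1998, 2)
#' ax$n_steps  # 92
#' @export
time_axis_8day <- function(start_year, n_years, steps_per_year = 46) {
  stopifnot(n_years >= 1, steps_per_year >= 1, steps_per_year * 8 <= 368)
  years <- rep(seq(start_year, length.out = n_years), each = steps_per_year)
  step <- rep(seq_len(steps_per_year), n_years)
  start <- as.Date(paste0(years, "-01-01")) + 8L * (step - 1L)
  year_end <- as.Date(paste0(years + 1L, "-01-01"))
  end <- pmin(start + 8L, year_end)
  center <- start + as.integer(floor(as.numeric(end - start) / 2))
  new_time_axis(start, center, end, years, step, 8L)
}

#' Daily time axis
#'
#' @param start_date first date (`Date` or ISO-8601 string).
#' @param n_days number of consecutive days.
#' @return A `time_axis` with one-day windows.
#' @export
time_axis_daily <- function(start_date, n_days) {
  stopifnot(n_days >= 1)
  start <- as.Date(start_date) + seq_len(n_days) - 1L
  yr <- as.integer(format(start, "%Y"))
  new_time_axis(start, start, start + 1L, yr,
                as.integer(format(start, "%j")), 1L)
}

new_time_axis <- function(start, center, end, year, step, step_days) {
  stopifnot(!is.unsorted(center, strictly = TRUE))
  structure(list(start = start, center = center, end = end,
                 year = year, step = step,
                 n_steps = length(center), step_days = step_days),
            class = "time_axis")
}

#' Rebuild a time axis from stored start/end dates
#'
#' Used when reading files back; infers year and within-year step.
#' @param start,end `Date` vectors of window starts and (exclusive) ends.
#' @return A `time_axis`.
#' @export
time_axis_from_dates <- function(start, end = start + 8L) {
  start <- as.Date(start); end <- as.Date(end)
  yr <- as.integer(format(start, "%Y"))
  jan1 <- as.Date(paste0(yr, "-01-01"))
  step <- as.integer(as.numeric(start - jan1) %/% 8) + 1L
  center <- start + as.integer(floor(as.numeric(end - start) / 2))
  new_time_axis(start, center, end, yr, step,
                as.integer(round(stats::median(as.numeric(end - start)))))
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> %d steps of %d day(s), %s .. %s\n",
              x$n_steps, x$step_days, format(x$center[1]),
              format(x$center[x$n_steps])))
  invisible(x)
}

#' Calendar month of each window center
#' @param axis a `time_axis`.
#' @return Integer vector of months (1-12).
#' @export
axis_month <- function(axis) as.integer(format(axis$center, "%m"))

#' Day of year of each window center
#' @param axis a `time_axis`.
#' @return Integer vector (1-366).
#' @export
axis_doy <- function(axis) as.integer(format(axis$center, "%j"))

same_axis <- function(a, b) {
  isTRUE(all.equal(as.numeric(a$center), as.numeric(b$center))) &&
    a$step_days == b$step_days
}
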