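#' Centered moving average with truncated end kernels
#'
#' Convolves a series with an odd-length symmetric weight vector summing
#' to one. Near the series ends (and next to masked values) the kernel is
#' truncated to the available points and renormalized. A window with no
#' valid point yields `NA`.
#'
#' @param series numeric vector (NA = masked).
#' @param weights odd-length symmetric numeric vector summing to 1.
#' @return Smoothed series of the same length.
#' @examples
#' centered_moving_average(c(0, 0, 3, 0, 0), rep(1, 3) / 3)  # 0 1 1 1 0
#' @export
centered_moving_average <- function(series, weights) {
  k <- length(weights)
  if (k %% 2 == 0) stop("weights must have odd length")
  if (!isTRUE(all.equal(weights, rev(weights))))
    stop("weights must be symmetric")
  if (abs(sum(weights)) < 1e-12) stop("weights must be normalizable")
  weights <- weights / sum(weights)
  half <- (k - 1) / 2
  n <- length(series)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    w <- weights[(lo - i + half + 1):(hi - i + half + 1)]
    x <- series[lo:hi]
    ok <- !is.na(x)
    if (any(ok)) out[i] <- sum(w[ok] * x[ok]) / sum(w[ok])
  }
  out
}

#' Henderson low-pass filter weights
#'
#' Closed-form symmetric weights of the (2h+1)-term Henderson filter.
#'
#' @param n_terms odd filter length (default 23).
#' @return Numeric weight vector summing to 1.
#' @export
henderson_weights <- function(n_terms = 23) {
  if (n_terms %% 2 == 0) stop("n_terms must be odd")
  h <- (n_terms - 1) / 2
  m <- h + 2
  j <- -h:h
  w <- 315 * ((m - 1)^2 - j^2) * (m^2 - j^2) * ((m + 1)^2 - j^2) *
    (3 * m^2 - 16 - 11 * j^2) /
    (8 * m * (m^2 - 1) * (4 * m^2 - 1) * (4 * m^2 - 9) * (4 * m^2 - 25))
  w / sum(w)
}

# Weights of the centered 2xp moving average: p+1 points, 1/(2p) at the
# ends and 1/p inside, so each of the p phases gets total weight 1/p.
ma_2xp_weights <- function(p) {
  c(1 / (2 * p), rep(1 / p, p - 1), 1 / (2 * p))
}

# Per-phase across-year smoothing of the detrended series with the 3x3
# composite filter (1,2,3,2,1)/9, then centering by removing its own 2xp
# moving average.
seasonal_estimate <- function(z, p) {
  s <- rep(NA_real_, length(z))
  w33 <- c(1, 2, 3, 2, 1) / 9
  for (phase in seq_len(p)) {
    idx <- seq(phase, length(z), by = p)
    s[idx] <- centered_moving_average(z[idx], w33)
  }
  s - centered_moving_average(s, ma_2xp_weights(p))
}

#' Census X-11 style seasonal-trend-irregular decomposition
#'
#' Two-pass additive scheme for 8-day series with `p` steps per year:
#' an initial trend from the centered 2xp moving average, a per-phase
#' seasonal estimate from the 3x3 composite filter (centered by its own
#' 2xp mean), a refined trend from the 23-point Henderson low-pass of the
#' deseasonalized series, and a second seasonal pass against that refined
#' trend. The final trend is the Henderson filter of `x - seasonal` and
#' the irregular is the exact residual, so
#' `trend + seasonal + irregular == x` at every unmasked step.
#'
#' @param series numeric vector, at least `3 * p` long (NA = masked).
#' @param p steps per year (period of the seasonal cycle).
#' @return A list of class `x11_decomposition` with `trend`, `seasonal`,
#'   `irregular` (aligned to the input) and `p`.
#' @export
x11_decompose <- function(series, p = 46) {
  x <- as.numeric(series)
  if (length(x) < 3 * p)
    stop("series must cover at least 3 full years (3 * p points)")
  w2p <- ma_2xp_weights(p)
  wh <- henderson_weights(23)
  t1 <- centered_moving_average(x, w2p)
  s1 <- seasonal_estimate(x - t1, p)
  t2 <- centered_moving_average(x - s1, wh)
  s2 <- seasonal_estimate(x - t2, p)
  trend <- centered_moving_average(x - s2, wh)
  irregular <- x - trend - s2
  structure(list(trend = trend, seasonal = s2, irregular = irregular,
                 p = p),
            class = "x11_decomposition")
}

#' @export
print.x11_decomposition <- function(x, ...) {
  cat(sprintf("<x11_decomposition> %d steps, period %d\n",
              length(x$trend), x$p))
  invisible(x)
}

#' Decompose every pixel of a gridded field
#'
#' @param field a `grid_field` on an 8-day axis.
#' @param p steps per year.
#' @return A list of `grid_field`s `trend`, `seasonal`, `irregular`.
#' @export
x11_decompose_field <- function(field, p = 46) {
  dm <- dim(field$values)
  tr <- se <- ir <- array(NA_real_, dm)
  for (i in seq_len(dm[2])) {
    for (j in seq_len(dm[3])) {
      d <- x11_decompose(field$values[, i, j], p)
      tr[, i, j] <- d$trend; se[, i, j] <- d$seasonal
      ir[, i, j] <- d$irregular
    }
  }
  mk <- function(nm, v) grid_field(paste0(field$name, "_", nm),
                                   field$units, field$lat, field$lon,
                                   field$axis, v)
  list(trend = mk("trend", tr), seasonal = mk("seasonal", se),
       irregular = mk("isv", ir))
}

#' Normalized intraseasonal-variability intensity map
#'
#' Per pixel: population standard deviation of the irregular (ISV)
#' component over the chosen season's steps across all years, divided by
#' that pixel's seasonal-mean SChl. Masked where the mean is
#' non-positive or fewer than `min_count` valid steps exist.
#'
#' @param bundle a `forcing_bundle`.
#' @param season `"winter"` (Jan-Feb) or `"spring"` (Mar-Apr).
#' @param p steps per year for the decomposition.
#' @param min_count minimum valid seasonal steps per pixel.
#' @return A `grid_field` of dimensionless ISV intensity (single time
#'   step).
#' @export
isv_std_map <- function(bundle, season = c("winter", "spring"),
                        p = 46, min_count = 6) {
  season <- match.arg(season)
  sel <- season_mask(bundle$schl$axis, season)
  dec <- x11_decompose_field(bundle$schl, p)
  dm <- dim(bundle$schl$values)
  out <- array(NA_real_, c(1, dm[2], dm[3]))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  for (i in seq_len(dm[2])) {
    for (j in seq_len(dm[3])) {
      isv <- dec$irregular$values[sel, i, j]
      schl <- bundle$schl$values[sel, i, j]
      ok <- !is.na(isv) & !is.na(schl)
      if (sum(ok) < min_count) next
      m <- mean(schl[ok])
      if (m <= 0) next
      out[1, i, j] <- pop_sd(isv[ok]) / m
    }
  }
  ax1 <- bundle$schl$axis
  one <- new_time_axis(ax1$start[1], ax1$center[1], ax1$end[1],
                       ax1$year[1], ax1$step[1], ax1$step_days)
  grid_field(paste0("schl_isv_std_", season), "1",
             bundle$schl$lat, bundle$schl$lon, one, out)
}
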