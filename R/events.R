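#' Phase classification of a pair of consecutive NHF values
#'
#' Classifies the 8-day interval `[t, t+1]` by the signs of the net heat
#' flux at its endpoints, with `NHF >= 0` counted as stable (a zero flux
#' means buoyancy loss has ceased):
#' (-,-) `WINTER_UNSTABLE`, (-,+) `TRANSITION_SHUTDOWN`,
#' (+,-) `TRANSITION_RESUME`, (+,+) `SPRING_STABLE`.
#'
#' @param nhf_t,nhf_t1 NHF at the first and second window, W m-2
#'   (vectorised; must be finite).
#' @return Character vector of phase labels.
#' @examples
#' classify_pair(-50, 30)  # "TRANSITION_SHUTDOWN"
#' @export
classify_pair <- function(nhf_t, nhf_t1) {
  if (any(!is.finite(nhf_t)) || any(!is.finite(nhf_t1)))
    stop("NHF values must be finite")
  ifelse(nhf_t < 0,
         ifelse(nhf_t1 < 0, "WINTER_UNSTABLE", "TRANSITION_SHUTDOWN"),
         ifelse(nhf_t1 < 0, "TRANSITION_RESUME", "SPRING_STABLE"))
}

#' Phase label of every interval of a series
#'
#' @param nhf NHF series.
#' @return Character vector of length `length(nhf) - 1`.
#' @export
classify_intervals <- function(nhf) {
  n <- length(nhf)
  classify_pair(nhf[-n], nhf[-1])
}

# Indices (within the full axis) of the January 1 - April 30 analysis
# window of one year: windows whose center falls on or before April 30.
analysis_window_indices <- function(axis, year) {
  apr30 <- as.integer(format(as.Date(paste0(year, "-04-30")), "%j"))
  which(axis$year == year & axis_doy(axis) <= apr30)
}

#' Detect NHF zero-crossings in the January-April window
#'
#' Scans each year's January 1 - April 30 window (windows whose center
#' falls inside it) for sign changes of NHF, with `NHF >= 0` counted as
#' positive. Negative-to-positive crossings are flagged persistent when
#' no later in-window step is negative.
#'
#' @param nhf NHF series on `axis`, W m-2.
#' @param axis the series' `time_axis`.
#' @return A data frame with one row per crossing: `year`, `index`
#'   (position in the full series of the first step on the new sign),
#'   `index_in_window`, `direction` (`"neg_pos"` or `"pos_neg"`) and
#'   `persistent`.
#' @export
find_zero_crossings <- function(nhf, axis) {
  stopifnot(length(nhf) == axis$n_steps)
  rows <- list()
  for (yr in unique(axis$year)) {
    idx <- analysis_window_indices(axis, yr)
    if (!length(idx)) stop("empty analysis window for year ", yr)
    x <- nhf[idx]
    pos <- !is.na(x) & x >= 0
    for (c in seq_along(x)[-1]) {
      if (is.na(x[c]) || is.na(x[c - 1])) next
      if (pos[c] == pos[c - 1]) next
      dir <- if (pos[c]) "neg_pos" else "pos_neg"
      persistent <- pos[c] && all(pos[c:length(x)])
      rows[[length(rows) + 1]] <- data.frame(
        year = yr, index = idx[c], index_in_window = c,
        direction = dir, persistent = persistent)
    }
  }
  if (!length(rows))
    return(data.frame(year = integer(), index = integer(),
                      index_in_window = integer(),
                      direction = character(), persistent = logical()))
  do.call(rbind, rows)
}

#' Last persistent negative-to-positive crossing of one year
#'
#' The convection-shutdown event: the final upward crossing after which
#' NHF remains nonnegative through April 30. At most one crossing per
#' year can satisfy persistence.
#'
#' @param events crossing table from [find_zero_crossings()], restricted
#'   to one pixel.
#' @param year the year to query.
#' @return A one-row data frame, or `NULL` when the year has none.
#' @export
last_persistent_crossing <- function(events, year) {
  sel <- events$year == year & events$direction == "neg_pos" &
    events$persistent
  if (!any(sel)) return(NULL)
  events[which(sel)[sum(sel)], , drop = FALSE]
}

#' Lag composite of net growth about shutdown events
#'
#' For each persistent negative-to-positive crossing at series index `c`,
#' the growth interval at lag `l` steps is `[c - 1 + l, c + l]`, so lag 0
#' spans the crossing itself. Lags whose interval falls outside the data
#' or starts before that year's analysis window are recorded as missing.
#' Contributions from all events are aggregated per lag.
#'
#' @param growth net growth-rate series on the intervals of `axis`
#'   (length `axis$n_steps - 1`), day-1.
#' @param events crossing table from [find_zero_crossings()]; only
#'   persistent neg-to-pos rows are used.
#' @param axis the `time_axis` of the underlying series.
#' @param lags lag offsets in steps (default -3..3, i.e. -24d..+24d).
#' @return A data frame with `lag_days`, `mean`, `sd`, `n` per lag.
#' @export
composite_about_crossing <- function(growth, events, axis, lags = -3:3) {
  vals <- composite_values(growth, events, lags)
  summarize_composite(vals, lags * axis$step_days)
}

# Raw growth contributions per lag (list parallel to lags); shared by
# composite_about_crossing and the pipeline's multi-pixel pooling.
composite_values <- function(growth, events, lags = -3:3) {
  ev <- events[events$direction == "neg_pos" & events$persistent, ,
               drop = FALSE]
  lapply(lags, function(l) {
    vals <- numeric(0)
    for (e in seq_len(nrow(ev))) {
      gi <- ev$index[e] - 1L + l
      win_start <- ev$index[e] - ev$index_in_window[e] + 1L
      if (gi < win_start || gi > length(growth)) next
      v <- growth[gi]
      if (!is.na(v)) vals <- c(vals, v)
    }
    vals
  })
}

summarize_composite <- function(vals, lag_days) {
  out <- data.frame(lag_days = lag_days, mean = NA_real_,
                    sd = NA_real_, n = vapply(vals, length, 0L))
  for (k in seq_along(vals)) {
    if (out$n[k] > 0) {
      out$mean[k] <- mean(vals[[k]])
      out$sd[k] <- if (out$n[k] > 1) stats::sd(vals[[k]]) else 0
    }
  }
  out
}

#' Default driver bin edges
#'
#' Nine equal-width bins spanning the central 98% of the driver values.
#' A degenerate driver (no spread over that range, as in noise-free
#' runs) collapses to a single narrow bin around the common value.
#'
#' @param driver numeric vector.
#' @param n_bins number of bins.
#' @param coverage central quantile mass covered.
#' @return Numeric vector of bin edges.
#' @export
default_bin_edges <- function(driver, n_bins = 9, coverage = 0.98) {
  q <- stats::quantile(driver, c((1 - coverage) / 2, 1 - (1 - coverage) / 2),
                       na.rm = TRUE, names = FALSE)
  if (q[1] >= q[2]) {
    delta <- max(1e-6, abs(q[1]) * 0.01)
    return(c(q[1] - delta, q[1] + delta))
  }
  seq(q[1], q[2], length.out = n_bins + 1)
}

#' Bin-averaged growth versus a stability driver
#'
#' Bins growth-rate intervals by the value of a driver derivative (for
#' example d(NHF)/dt), optionally restricted to a set of phase labels,
#' and returns the per-bin mean, standard deviation and count. Bins with
#' fewer than `min_count` intervals are flagged unreliable.
#'
#' @param growth net growth per interval, day-1.
#' @param driver driver value per interval (same length).
#' @param labels optional phase labels per interval (from
#'   [classify_intervals()]).
#' @param phases optional character vector of labels to keep.
#' @param keep optional extra logical mask on intervals.
#' @param edges bin edges, strictly increasing; default
#'   [default_bin_edges()] of the selected driver values.
#' @param min_count reliability threshold.
#' @return A data frame with `bin_lo`, `bin_hi`, `bin_center`, `mean`,
#'   `sd`, `n`, `reliable`.
#' @export
bin_relation <- function(growth, driver, labels = NULL, phases = NULL,
                         keep = NULL, edges = NULL, min_count = 10) {
  stopifnot(length(growth) == length(driver))
  sel <- !is.na(growth) & !is.na(driver)
  if (!is.null(phases)) {
    if (is.null(labels)) stop("phase filtering requires 'labels'")
    sel <- sel & labels %in% phases
  }
  if (!is.null(keep)) sel <- sel & keep
  g <- growth[sel]; d <- driver[sel]
  if (is.null(edges)) edges <- default_bin_edges(d)
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  bin <- findInterval(d, edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  nb <- length(edges) - 1
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  out$bin_center <- (out$bin_lo + out$bin_hi) / 2
  out$mean <- NA_real_; out$sd <- NA_real_; out$n <- 0L
  for (b in seq_len(nb)) {
    v <- g[bin == b]
    out$n[b] <- length(v)
    if (length(v)) {
      out$mean[b] <- mean(v)
      out$sd[b] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  out$reliable <- out$n >= min_count
  out
}
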