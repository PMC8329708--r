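#' Bin spike times into a fixed-width rate series
#'
#' Counts spikes in half-open bins `[t0 + i*w, t0 + (i+1)*w)` and converts
#' to rates (counts / bin width). 100 ms bins are the pipeline default.
#'
#' @param spike_times numeric spike times in seconds.
#' @param t0,t1 range covered, `t1 > t0`; spikes outside `[t0, t1)` are
#'   ignored.
#' @param bin_width_s bin width in seconds (default 0.1).
#' @return an object of class `rate_series`: list with `start_t_s`,
#'   `bin_width_s`, `counts`, `rates`, `t_s` (bin centers).
#' @export
bin_rates <- function(spike_times, t0, t1, bin_width_s = 0.1) {
  if (t1 <= t0) stop("t1 must exceed t0")
  w <- bin_width_s
  nbins <- as.integer(ceiling((t1 - t0) / w - 1e-9))
  s <- spike_times[spike_times >= t0 & spike_times < t0 + nbins * w]
  idx <- floor((s - t0) / w) + 1
  counts <- tabulate(idx, nbins = nbins)
  structure(
    list(start_t_s = t0, bin_width_s = w, counts = counts,
         rates = counts / w,
         t_s = t0 + (seq_len(nbins) - 0.5) * w),
    class = "rate_series"
  )
}

#' Centered rolling-mean smoothing of a rate series
#'
#' A rolling mean over `window_s` (30 bins at the defaults), truncated at
#' the edges. Intended for visualization only; correlation analyses use the
#' raw binned rates.
#'
#' @param series a `rate_series` or numeric vector of rates.
#' @param window_s smoothing window in seconds (default 3).
#' @param bin_width_s bin width when `series` is a bare vector.
#' @return object of the same kind as the input, with smoothed `rates`.
#' @export
smooth_rates <- function(series, window_s = 3.0, bin_width_s = 0.1) {
  is_rs <- inherits(series, "rate_series")
  rates <- if (is_rs) series$rates else series
  w <- if (is_rs) series$bin_width_s else bin_width_s
  if (window_s < w) stop("window must be at least one bin wide")
  k <- max(1L, round(window_s / w))
  n <- length(rates)
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  cs <- cumsum(c(0, rates))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  if (is_rs) {
    out <- series
    out$rates <- sm
    out$counts <- NULL
    out
  } else {
    sm
  }
}

#' Segment a flight into trefoil repetitions
#'
#' Finds entries into the start region (a disk around the lift-off corner)
#' while the copter moves on the initial bearing, and delimits repetitions
#' by consecutive entries. The period before the first entry and after the
#' last entry (start-up and landing) is excluded.
#'
#' @param telemetry a [telemetry_track].
#' @param start_center numeric `c(x, y)` of the start region, meters.
#' @param start_radius region radius in meters.
#' @param bearing_rad initial bearing; defaults to the yaw at the first
#'   sample inside the region. Entries require yaw within 90 degrees of it.
#' @param min_gap_s minimum time between successive entries (default 10).
#' @return data.frame with columns `start_s`, `end_s`, one row per
#'   repetition (zero rows, with a warning, when none is found).
#' @export
segment_repetitions <- function(telemetry, start_center, start_radius = 10,
                                bearing_rad = NULL, min_gap_s = 10) {
  d <- sqrt((telemetry$x_m - start_center[1])^2 +
            (telemetry$y_m - start_center[2])^2)
  inside <- d <= start_radius
  if (!any(inside)) {
    warning("no telemetry samples inside the start region")
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  if (is.null(bearing_rad)) bearing_rad <- telemetry$yaw_rad[which(inside)[1]]
  on_bearing <- abs(angle_diff(telemetry$yaw_rad, bearing_rad)) < pi / 2
  state <- inside & on_bearing
  entry <- state & !c(FALSE, state[-length(state)])
  entry_t <- telemetry$t_s[entry]
  if (length(entry_t) > 1) {
    keep <- c(TRUE, diff(entry_t) >= min_gap_s)
    entry_t <- entry_t[keep]
  }
  if (length(entry_t) < 2) {
    warning("fewer than two start-region entries; no complete repetition")
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  data.frame(start_s = entry_t[-length(entry_t)], end_s = entry_t[-1])
}

angle_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  d
}

#' Sliding autocorrelation of a rate series against one repetition
#'
#' Pearson correlation between the rate vector of a single repetition
#' (the template interval) and every equal-length window of the series, one
#' value per offset. Windows with zero variance yield `r = 0`. When the
#' spike rate tracks the repeated trajectory, peaks appear at the start of
#' every repetition.
#'
#' @param series a `rate_series` or numeric rate vector.
#' @param template_interval numeric `c(start_s, end_s)` of the template
#'   repetition on the series' time axis, or (for a bare vector) integer
#'   `c(first_bin, last_bin)`.
#' @return data.frame with `offset_s` (or `offset_bins`) and `r`.
#' @export
sliding_autocorrelation <- function(series, template_interval) {
  if (inherits(series, "rate_series")) {
    w <- series$bin_width_s
    i0 <- floor((template_interval[1] - series$start_t_s) / w) + 1
    i1 <- floor((template_interval[2] - series$start_t_s - 1e-9) / w) + 1
    rates <- series$rates
  } else {
    rates <- series
    i0 <- template_interval[1]
    i1 <- template_interval[2]
    w <- NA_real_
  }
  i0 <- max(1L, as.integer(i0))
  if (i1 > length(rates)) {
    stop("template interval is longer than the series")
  }
  i1 <- as.integer(i1)
  template <- rates[i0:i1]
  L <- length(template)
  n <- length(rates)
  if (L > n) stop("template longer than series")
  if (L < 3) stop("template too short")
  offsets <- 0:(n - L)
  st <- stats::sd(template)
  r <- vapply(offsets, function(o) {
    win <- rates[(o + 1):(o + L)]
    sw <- stats::sd(win)
    if (st == 0 || sw == 0) return(0)
    stats::cor(template, win)
  }, numeric(1))
  if (is.na(w)) {
    data.frame(offset_bins = offsets, r = r)
  } else {
    data.frame(offset_s = offsets * w, r = r)
  }
}

#' Bin-averaged yaw-rate series on the rate grid
#'
#' Resamples telemetry yaw rate onto the 100-ms rate grid by averaging
#' (absolute) yaw rate over each bin, producing the behavioral regressor for
#' [lagged_crosscorr()].
#'
#' @param telemetry a [telemetry_track].
#' @param t0,t1 covered range, seconds.
#' @param bin_width_s bin width (default 0.1).
#' @param absolute use `|yaw rate|` (default TRUE; turning speed regardless
#'   of direction).
#' @return numeric vector, one value per bin.
#' @export
bin_yaw_rate <- function(telemetry, t0, t1, bin_width_s = 0.1,
                         absolute = TRUE) {
  nbins <- as.integer(ceiling((t1 - t0) / bin_width_s - 1e-9))
  sel <- telemetry$t_s >= t0 & telemetry$t_s < t0 + nbins * bin_width_s
  tt <- telemetry$t_s[sel]
  yr <- telemetry$yaw_rate_rad_s[sel]
  if (absolute) yr <- abs(yr)
  idx <- floor((tt - t0) / bin_width_s) + 1
  sums <- tapply(yr, factor(idx, levels = seq_len(nbins)), mean)
  out <- as.numeric(sums)
  # fill bins without telemetry samples by interpolation
  if (anyNA(out)) {
    ok <- which(!is.na(out))
    out <- stats::approx(ok, out[ok], xout = seq_len(nbins), rule = 2)$y
  }
  out
}

#' Lagged cross-correlation between spike rate and yaw rate
#'
#' Pearson correlation at every lag in `[-max_lag_s, +max_lag_s]` on the
#' shared 100-ms grid. Positive lag means the spike rate follows the
#' behavior (neural activity lags turning). Overlap shrinks with lag (no
#' padding); lags with fewer than `min_overlap` bins are omitted. The peak
#' is the lag maximizing `r`.
#'
#' @param rate numeric rate vector or `rate_series`.
#' @param yaw_rate numeric behavioral vector on the same grid (see
#'   [bin_yaw_rate()]).
#' @param max_lag_s maximum lag searched, seconds.
#' @param step_s lag step (default 0.1, one bin).
#' @param min_overlap minimum number of overlapping bins per lag.
#' @return object of class `crosscorr_result`: list with `lags_s`,
#'   `r_at_lag`, `peak_lag_s`, `peak_r`.
#' @export
lagged_crosscorr <- function(rate, yaw_rate, max_lag_s = 3, step_s = 0.1,
                             min_overlap = 10) {
  if (inherits(rate, "rate_series")) rate <- rate$rates
  if (max_lag_s < step_s) stop("max_lag_s must be at least step_s")
  n <- length(rate)
  if (length(yaw_rate) != n) stop("series must share the same grid")
  ks <- seq(-round(max_lag_s / step_s), round(max_lag_s / step_s))
  lags <- ks * step_s
  r <- rep(NA_real_, length(ks))
  for (m in seq_along(ks)) {
    k <- ks[m]
    if (k >= 0) {
      a <- rate[(1 + k):n]
      b <- yaw_rate[1:(n - k)]
    } else {
      a <- rate[1:(n + k)]
      b <- yaw_rate[(1 - k):n]
    }
    if (length(a) < min_overlap) next
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      r[m] <- 0
    } else {
      r[m] <- stats::cor(a, b)
    }
  }
  ok <- !is.na(r)
  lags <- lags[ok]
  r <- r[ok]
  ipk <- which.max(r)
  structure(
    list(lags_s = lags, r_at_lag = r,
         peak_lag_s = lags[ipk], peak_r = r[ipk]),
    class = "crosscorr_result"
  )
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf("crosscorr_result: peak r = %.3f at lag %.2f s (%d lags)\n",
              x$peak_r, x$peak_lag_s, length(x$lags_s)))
  invisible(x)
}
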