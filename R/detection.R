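#' Threshold spike detection by local minima
#'
#' Detects negative-going spikes as local minima of a (locally normalized)
#' signal below `-Thr` with `Thr = multiplier * robust_noise(x)`. Candidate
#' minima closer together than half a waveform window are resolved by
#' keeping the deeper trough.
#'
#' @param x numeric vector, locally normalized (see
#'   [local_robust_normalize()]).
#' @param sample_rate_hz sampling rate in Hz.
#' @param multiplier threshold multiplier (4 by default).
#' @param start_time_s time of sample 1, seconds.
#' @param window_s waveform window length used to derive the minimum
#'   trough separation (half-width).
#' @param positive_peaks detect positive peaks instead (sign-flipped mode).
#' @return a data.frame of spike events: `t_s`, `sample_index`,
#'   `trough_amplitude`, `origin` (= "threshold"). Attribute `threshold`
#'   carries the absolute threshold used.
#' @export
detect_spikes <- function(x, sample_rate_hz = 20000, multiplier = 4,
                          start_time_s = 0, window_s = 0.00144,
                          positive_peaks = FALSE) {
  if (inherits(x, "clean_signal")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- x$samples
  }
  if (positive_peaks) x <- -x
  n_est <- robust_noise(x)
  if (n_est == 0) stop("degenerate signal: robust noise is zero")
  thr <- multiplier * n_est
  half_width <- waveform_half_width(sample_rate_hz, window_s)
  idx <- local_minima_below(x, -thr)
  idx <- suppress_close(idx, depth = x[idx], min_sep = half_width,
                        n = length(x))
  amp <- x[idx]
  if (positive_peaks) amp <- -amp
  out <- data.frame(
    t_s = start_time_s + (idx - 1) / sample_rate_hz,
    sample_index = idx,
    trough_amplitude = amp,
    origin = rep("threshold", length(idx)),
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  out
}

# indices of strict-left / non-strict-right local minima below `cut`
local_minima_below <- function(x, cut) {
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- x[2:(n - 1)]
  which(core < x[1:(n - 2)] & core <= x[3:n] & core < cut) + 1L
}

# greedy suppression: keep deeper troughs, block +/- (min_sep - 1) samples
suppress_close <- function(idx, depth, min_sep, n) {
  if (length(idx) < 2) return(idx)
  ord <- order(depth)  # most negative (deepest) first
  blocked <- logical(n)
  keep <- logical(length(idx))
  for (k in ord) {
    i <- idx[k]
    if (!blocked[i]) {
      keep[k] <- TRUE
      lo <- max(1L, i - min_sep + 1L)
      hi <- min(n, i + min_sep - 1L)
      blocked[lo:hi] <- TRUE
    }
  }
  sort(idx[keep])
}

waveform_half_width <- function(sample_rate_hz, window_s = 0.00144) {
  w <- waveform_length(sample_rate_hz, window_s)
  (w - 1L) %/% 2L
}

# 1.44 ms at 20 kHz = 28.8 samples -> rounded up to the next odd length, 29,
# so the window is symmetric around the trough
waveform_length <- function(sample_rate_hz, window_s = 0.00144) {
  w <- as.integer(ceiling(window_s * sample_rate_hz))
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 3L)
}

#' Extract trough-centered waveform windows
#'
#' Cuts a fixed-length window (1.44 ms; 29 samples at 20 kHz) around each
#' detected trough. Events too close to the signal edges for a full window
#' are dropped and counted.
#'
#' With `align = TRUE` (the default) each window is re-centered on the
#' continuous centroid of the trough lobe (samples below half the trough
#' depth) and resampled at the fractional shift by linear interpolation.
#' For broad spikes the deepest sample alternates between neighboring
#' samples under noise, which would split one unit's waveforms into
#' discrete shape classes; the continuous centroid is stable against that.
#'
#' @param x numeric signal (or `clean_signal`).
#' @param events spike-event data.frame from [detect_spikes()] or
#'   [template_matching_detect()].
#' @param sample_rate_hz sampling rate in Hz.
#' @param window_s window length in seconds.
#' @param align re-center windows on the trough centroid.
#' @return list with `events` (retained rows), `waveforms` (matrix, one row
#'   per retained event), and `n_dropped`.
#' @export
extract_waveforms <- function(x, events, sample_rate_hz = 20000,
                              window_s = 0.00144, align = TRUE) {
  if (inherits(x, "clean_signal")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- x$samples
  }
  w <- waveform_length(sample_rate_hz, window_s)
  half <- (w - 1L) %/% 2L
  n <- length(x)
  margin <- if (align) half + 6L else half
  ok <- events$sample_index - margin >= 1L & events$sample_index + margin <= n
  kept <- events[ok, , drop = FALSE]
  wf <- matrix(0, nrow = nrow(kept), ncol = w)
  offs <- -half:half
  for (k in seq_len(nrow(kept))) {
    c0 <- kept$sample_index[k]
    if (align) {
      local <- x[(c0 - 4L):(c0 + 4L)]
      depth <- min(local)
      lobe <- which(local <= depth / 2)
      wts <- -local[lobe]
      shift <- sum((lobe - 5L) * wts) / sum(wts)
      pos <- c0 + shift + offs
      i <- floor(pos)
      f <- pos - i
      wf[k, ] <- x[i] * (1 - f) + x[i + 1L] * f
    } else {
      wf[k, ] <- x[c0 + offs]
    }
  }
  list(events = kept, waveforms = wf, n_dropped = sum(!ok))
}

#' Median spike template
#'
#' Per-sample median across a set of waveforms; robust to a minority of
#' corrupted or overlapping spikes.
#'
#' @param waveforms matrix, one waveform per row.
#' @return numeric vector of the per-sample median.
#' @export
median_template <- function(waveforms) {
  if (is.null(dim(waveforms))) waveforms <- matrix(waveforms, nrow = 1)
  if (nrow(waveforms) == 0) stop("no waveforms")
  apply(waveforms, 2, stats::median)
}

#' Template-matching spike re-detection
#'
#' Computes the sliding Pearson correlation of a unit's median template with
#' the normalized signal and repeats threshold detection on the correlation
#' series: a threshold of `multiplier * robust_noise(c)` is applied to the
#' positive side and local maxima above it become events. Because Pearson
#' correlation is amplitude-invariant, this recovers spikes whose shape is
#' intact but whose amplitude falls below the amplitude threshold during
#' high-noise episodes. New events within `dedup_s` of an existing event are
#' discarded; existing events are never removed.
#'
#' @param x numeric signal (or `clean_signal`), locally normalized.
#' @param template numeric template (one waveform length).
#' @param existing_events spike-event data.frame to deduplicate against.
#' @param sample_rate_hz sampling rate in Hz.
#' @param multiplier threshold multiplier on the correlation series.
#' @param dedup_s half-width of the deduplication window in seconds
#'   (default 2 ms, half the 4 ms refractory period).
#' @param start_time_s time of sample 1, seconds.
#' @return a data.frame of new spike events with `origin = "template"`.
#' @export
template_matching_detect <- function(x, template, existing_events = NULL,
                                     sample_rate_hz = 20000, multiplier = 4,
                                     dedup_s = 0.002, start_time_s = 0) {
  if (inherits(x, "clean_signal")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- x$samples
  }
  cc <- sliding_pearson(x, template)
  n_c <- robust_noise(cc[is.finite(cc)])
  if (n_c == 0) stop("degenerate correlation series")
  thr <- multiplier * n_c
  half_width <- (length(template) - 1L) %/% 2L
  # local maxima of the correlation series above threshold
  neg <- -cc
  idx <- local_minima_below(neg, -thr)
  idx <- suppress_close(idx, depth = neg[idx], min_sep = half_width,
                        n = length(x))
  if (!is.null(existing_events) && nrow(existing_events) > 0 &&
      length(idx) > 0) {
    dedup_samp <- round(dedup_s * sample_rate_hz)
    keep <- vapply(idx, function(i) {
      min(abs(existing_events$sample_index - i)) > dedup_samp
    }, logical(1))
    idx <- idx[keep]
  }
  data.frame(
    t_s = start_time_s + (idx - 1) / sample_rate_hz,
    sample_index = idx,
    trough_amplitude = x[idx],
    origin = rep("template", length(idx)),
    stringsAsFactors = FALSE
  )
}

#' Sliding Pearson correlation of a template with a signal
#'
#' For every alignment of the template, the Pearson correlation between the
#' template and the signal window centered at that sample. Alignments whose
#' window has (near-)zero variance yield 0; edge samples without a full
#' window yield 0.
#'
#' @param x numeric signal.
#' @param template numeric template, odd length.
#' @return numeric vector, same length as `x`.
#' @export
sliding_pearson <- function(x, template) {
  w <- length(template)
  n <- length(x)
  if (w > n) stop("template longer than signal")
  tc <- template - mean(template)
  st2 <- sum(tc^2)
  if (st2 == 0) stop("constant template")
  # rolling sums via convolution filters; value at i = window ending at i
  ones <- rep(1, w)
  sx  <- stats::filter(x, ones, method = "convolution", sides = 1)
  sxx <- stats::filter(x * x, ones, method = "convolution", sides = 1)
  cross <- stats::filter(x, rev(tc), method = "convolution", sides = 1)
  varw <- sxx - sx^2 / w
  r_end <- as.numeric(cross) / sqrt(pmax(varw, 0) * st2)
  r_end[!is.finite(r_end)] <- 0
  r_end[varw <= st2 * 1e-12] <- 0
  # shift so value sits at the window center
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  out[seq(w - half, n - half)] <- r_end[seq(w, n)]
  out
}

#' Match detected spike times against reference times
#'
#' Greedy chronological matching of two sorted spike-time lists with a
#' tolerance, yielding precision/recall/F1. Used to score detection against
#' generator ground truth.
#'
#' @param detected_t,truth_t numeric vectors of spike times in seconds.
#' @param tol_s matching tolerance in seconds (default 1 ms).
#' @return list with `n_matched`, `precision`, `recall`, `f1`.
#' @export
match_spike_times <- function(detected_t, truth_t, tol_s = 0.001) {
  d <- sort(detected_t)
  tr <- sort(truth_t)
  i <- 1L; j <- 1L; m <- 0L
  while (i <= length(d) && j <= length(tr)) {
    dt <- d[i] - tr[j]
    if (abs(dt) <= tol_s) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (dt < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  precision <- if (length(d) > 0) m / length(d) else 0
  recall <- if (length(tr) > 0) m / length(tr) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(n_matched = m, precision = precision, recall = recall, f1 = f1)
}
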