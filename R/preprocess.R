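#' Robust (median/MAD) normalization
#'
#' Centers a signal by its median and scales by its unscaled median absolute
#' deviation: `(x - median(x)) / median(|x - median(x)|)`. This is the
#' global normalization applied to each monopolar channel before channel
#' subtraction. Note the MAD here is *unscaled*; the 1.4826 Gaussian
#' consistency factor enters only in the noise estimate used for
#' thresholding ([robust_noise()]).
#'
#' @param x numeric vector, length >= 2.
#' @return normalized vector with median 0 and unscaled MAD 1.
#' @export
robust_normalize <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  med <- stats::median(x)
  m <- stats::median(abs(x - med))
  if (m == 0) stop("degenerate signal: MAD is zero")
  (x - med) / m
}

#' Robust noise estimate used for gain tuning and thresholding
#'
#' `n = median(|x - median(x)|) * 1.4826`, a robust estimate of the Gaussian
#' standard deviation of the background noise that is insensitive to the
#' spikes riding on it.
#'
#' @param x numeric vector.
#' @return scalar noise estimate.
#' @export
robust_noise <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  med <- stats::median(x)
  stats::median(abs(x - med)) * 1.4826
}

#' Estimate the channel-subtraction gain
#'
#' The two monopolar channels see the copter's common-mode noise with
#' different effective gains (electrode impedances differ), so the
#' differential `a - g*b` cancels it best at a channel-specific `g`.
#' This chooses `g` minimizing the robust noise of the residual over a
#' coarse grid, then refines by golden-section search around the grid
#' minimum. Ties on the grid go to the smallest `g`.
#'
#' For long recordings the robust-noise objective is evaluated on a strided
#' subsample (at most `max_eval_samples` points); the objective is a global
#' scale statistic, so a deterministic stride does not bias the minimizer.
#'
#' @param ch_a,ch_b equal-length numeric vectors.
#' @param gain_grid numeric grid of candidate gains (default `seq(0, 4, 0.01)`).
#' @param refine_tol absolute tolerance of the golden-section refinement.
#' @param max_eval_samples cap on the number of samples used in each
#'   objective evaluation.
#' @return the estimated gain, a scalar.
#' @export
estimate_subtraction_gain <- function(ch_a, ch_b,
                                      gain_grid = seq(0, 4, by = 0.01),
                                      refine_tol = 1e-4,
                                      max_eval_samples = 200000L) {
  if (length(ch_a) != length(ch_b)) stop("channel lengths differ")
  if (length(gain_grid) < 1) stop("gain grid is empty")
  n <- length(ch_a)
  if (n > max_eval_samples) {
    idx <- seq(1L, n, by = ceiling(n / max_eval_samples))
    a <- ch_a[idx]; b <- ch_b[idx]
  } else {
    a <- ch_a; b <- ch_b
  }
  obj <- function(g) robust_noise(a - g * b)
  vals <- vapply(gain_grid, obj, numeric(1))
  i <- which(vals == min(vals))[1]  # ties -> smallest g (grid is ascending)
  # golden-section refinement within one grid step of the coarse minimum
  lo <- gain_grid[max(1L, i - 1L)]
  hi <- gain_grid[min(length(gain_grid), i + 1L)]
  if (hi <= lo) return(gain_grid[i])
  golden_section(obj, lo, hi, tol = refine_tol)
}

golden_section <- function(f, lo, hi, tol = 1e-4) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while ((hi - lo) > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- f(x2)
    }
  }
  (lo + hi) / 2
}

#' Differential of the two channels
#'
#' Pointwise `ch_a - g * ch_b`, the digital-domain subtraction that removes
#' gain-mismatched common-mode noise while preserving spikes (which appear
#' with opposite polarity on the two electrodes).
#'
#' @param ch_a,ch_b equal-length numeric vectors.
#' @param g subtraction gain, typically from [estimate_subtraction_gain()].
#' @param sample_rate_hz sampling rate carried into the result.
#' @return an object of class `clean_signal`: list with `samples`,
#'   `sample_rate_hz`, `gain_g`, `provenance`.
#' @export
differential <- function(ch_a, ch_b, g, sample_rate_hz = 20000) {
  if (length(ch_a) != length(ch_b)) stop("channel lengths differ")
  structure(
    list(samples = ch_a - g * ch_b,
         sample_rate_hz = sample_rate_hz,
         gain_g = g,
         provenance = list(op = "differential", g = g)),
    class = "clean_signal"
  )
}

#' Local robust normalization with a sliding window
#'
#' Normalizes each sample by the median and unscaled MAD of a centered
#' window (default 1 s) so that spike amplitudes are expressed relative to
#' the *local* noise floor, compensating the time-varying signal-to-noise
#' ratio caused by the copter's motors and rotors. Window statistics are
#' computed at a regular hop (default 50 ms) and linearly interpolated
#' between hop centers; windows are truncated at the edges. A window with
#' zero MAD falls back to the global MAD with a warning.
#'
#' @param x numeric vector or `clean_signal`.
#' @param sample_rate_hz sampling rate in Hz (ignored when `x` is a
#'   `clean_signal`).
#' @param window_s window length in seconds.
#' @param hop_s spacing of window centers in seconds.
#' @return numeric vector of locally normalized samples.
#' @export
local_robust_normalize <- function(x, sample_rate_hz = 20000, window_s = 1.0,
                                   hop_s = 0.05) {
  if (inherits(x, "clean_signal")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- x$samples
  }
  n <- length(x)
  half <- round(window_s * sample_rate_hz / 2)
  if (2 * half < 2) stop("window too short: window_s * rate must be >= 2")
  hop <- max(1L, round(hop_s * sample_rate_hz))
  centers <- unique(c(seq(1L, n, by = hop), n))
  meds <- numeric(length(centers))
  mads <- numeric(length(centers))
  for (k in seq_along(centers)) {
    i0 <- max(1L, centers[k] - half)
    i1 <- min(n, centers[k] + half)
    w <- x[i0:i1]
    m <- stats::median(w)
    meds[k] <- m
    mads[k] <- stats::median(abs(w - m))
  }
  if (any(mads == 0)) {
    gmad <- stats::median(abs(x - stats::median(x)))
    if (gmad == 0) stop("degenerate signal: global MAD is zero")
    warning("window(s) with zero MAD; substituting global MAD")
    mads[mads == 0] <- gmad
  }
  if (length(centers) == 1) {
    return((x - meds[1]) / mads[1])
  }
  med_i <- stats::approx(centers, meds, xout = seq_len(n), rule = 2)$y
  mad_i <- stats::approx(centers, mads, xout = seq_len(n), rule = 2)$y
  (x - med_i) / mad_i
}
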