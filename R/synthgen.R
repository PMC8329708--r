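#' Parametric extracellular spike templates
#'
#' Negative-going (dominant trough) biphasic waveforms: a narrow Gaussian
#' trough followed by a broader positive rebound, normalized to a trough of
#' -1. Varying the trough width, rebound size and rebound delay yields
#' distinguishable unit templates.
#'
#' @param n_samples template length (29 = 1.44 ms at 20 kHz).
#' @param trough_width_samples Gaussian sigma of the trough, in samples.
#' @param rebound relative amplitude of the positive rebound.
#' @param rebound_delay_samples delay of the rebound peak after the trough.
#' @param rebound_width_samples Gaussian sigma of the rebound.
#' @return numeric template of length `n_samples` with minimum -1.
#' @export
make_spike_template <- function(n_samples = 29, trough_width_samples = 2.5,
                                rebound = 0.5, rebound_delay_samples = 6,
                                rebound_width_samples = 5) {
  s <- seq_len(n_samples) - (n_samples + 1) / 2
  w <- -exp(-(s / trough_width_samples)^2) +
    rebound * exp(-((s - rebound_delay_samples) / rebound_width_samples)^2)
  w / abs(min(w))
}

#' Default template bank for three synthetic units
#'
#' @param n_samples template length.
#' @return list of three distinct templates.
#' @export
default_templates <- function(n_samples = 29) {
  list(
    make_spike_template(n_samples, trough_width_samples = 2.0,
                        rebound = 0.55, rebound_delay_samples = 5,
                        rebound_width_samples = 4),
    make_spike_template(n_samples, trough_width_samples = 3.5,
                        rebound = 0.35, rebound_delay_samples = 8,
                        rebound_width_samples = 6),
    make_spike_template(n_samples, trough_width_samples = 5.0,
                        rebound = 0.6, rebound_delay_samples = 10,
                        rebound_width_samples = 3)
  )
}

unit_vec <- function(theta) c(cos(theta), sin(theta))

# smallest arc angle phi > 0 (or 0) such that after turning by phi on a
# circle of radius r (clockwise when dir = -1, counterclockwise when
# dir = +1) the heading points at `target`
solve_arc <- function(pos, heading, r, target, dir = -1) {
  ctr <- pos + r * unit_vec(heading + dir * pi / 2)
  f <- function(phi) {
    p <- ctr + r * unit_vec(heading - dir * pi / 2 + dir * phi)
    aim <- atan2(target[2] - p[2], target[1] - p[1])
    angle_diff(aim, heading + dir * phi)
  }
  if (abs(f(0)) < 1e-9) return(0)
  phis <- seq(0, 2 * pi, length.out = 721)
  vals <- vapply(phis, f, numeric(1))
  sgn <- sign(vals)
  for (i in seq_len(length(phis) - 1)) {
    if (sgn[i] != sgn[i + 1] && abs(vals[i] - vals[i + 1]) < pi) {
      return(stats::uniroot(f, c(phis[i], phis[i + 1]), tol = 1e-10)$root)
    }
  }
  stop("no arc solution; target may be inside the turning circle")
}

# path-building primitives: segments are either straight lines or clockwise
# arcs, each carrying its arc length so the path can be sampled at constant
# speed
seg_straight <- function(p0, p1) {
  list(type = "straight", p0 = p0, p1 = p1,
       heading = atan2(p1[2] - p0[2], p1[1] - p0[1]),
       len = sqrt(sum((p1 - p0)^2)))
}

seg_arc <- function(pos, heading, r, phi, dir = -1) {
  ctr <- pos + r * unit_vec(heading + dir * pi / 2)
  list(type = "arc", center = ctr, r = r, heading0 = heading, phi = phi,
       dir = dir, len = r * phi)
}

seg_end <- function(seg) {
  if (seg$type == "straight") {
    list(pos = seg$p1, heading = seg$heading)
  } else {
    seg_at(seg, seg$len)
  }
}

seg_at <- function(seg, s) {
  if (seg$type == "straight") {
    f <- if (seg$len > 0) s / seg$len else 0
    list(pos = seg$p0 + f * (seg$p1 - seg$p0), heading = seg$heading)
  } else {
    phi <- s / seg$r
    list(pos = seg$center +
           seg$r * unit_vec(seg$heading0 - seg$dir * pi / 2 + seg$dir * phi),
         heading = seg$heading0 + seg$dir * phi)
  }
}

#' Generate trefoil flight telemetry
#'
#' Builds the three-lobed flight pattern of the field experiments: from the
#' start corner straight over the feeder and `leg_beyond_m` past it, then a
#' clockwise (right) turn that reorients the copter back toward the feeder
#' from a new bearing; after three feeder overflights per repetition the
#' copter returns to the start corner via a turnaround waypoint behind it,
#' so it re-enters the start region already on the initial bearing. Lobes
#' are straight legs joined by circular arcs of configurable radius, flown
#' at constant speed and altitude and sampled at `sample_hz`.
#'
#' @param speed_m_s flight speed (default 5.5 m/s).
#' @param altitude_m flight altitude (default 15 m).
#' @param start_xy start-corner coordinates, meters.
#' @param feeder_xy feeder coordinates, meters.
#' @param leg_beyond_m distance flown past the feeder before the turn
#'   (default 80 m).
#' @param n_repetitions number of trefoil repetitions (default 3).
#' @param turn_radius_m radius of the clockwise turn arcs (default 10 m).
#' @param turnaround_behind_m distance of the return waypoint behind the
#'   start corner along the start-feeder axis (default 40 m).
#' @param start_region_radius_m radius of the start region used to define
#'   repetition bounds (default 10 m).
#' @param sample_hz telemetry rate (default 100).
#' @param seed unused (the geometry is deterministic); accepted for
#'   interface uniformity.
#' @return list with `telemetry` (a [telemetry_track]) and
#'   `repetition_bounds` (matrix with columns `start_s`, `end_s`).
#' @export
gen_trefoil_telemetry <- function(speed_m_s = 5.5, altitude_m = 15,
                                  start_xy = c(0, 0), feeder_xy = c(0, 150),
                                  leg_beyond_m = 80, n_repetitions = 3,
                                  turn_radius_m = 10,
                                  turnaround_behind_m = 40,
                                  start_region_radius_m = 10,
                                  sample_hz = 100, seed = NULL) {
  if (speed_m_s <= 0 || altitude_m <= 0 || leg_beyond_m <= 0 ||
      turn_radius_m <= 0 || sample_hz <= 0) {
    stop("geometry parameters must be positive")
  }
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  start <- as.numeric(start_xy)
  feeder <- as.numeric(feeder_xy)
  u0 <- atan2(feeder[2] - start[2], feeder[1] - start[1])
  behind <- start - turnaround_behind_m * unit_vec(u0)
  r <- turn_radius_m

  # steer onto a target: turn on an arc until the heading points at it,
  # then fly straight. The trefoil lobe turns are right (clockwise) turns;
  # alignment steers take whichever direction needs the smaller arc.
  steer_to <- function(pos, heading, target, direction = c("auto", "cw")) {
    direction <- match.arg(direction)
    segs <- list()
    phi_cw <- solve_arc(pos, heading, r, target, dir = -1)
    if (direction == "cw") {
      phi <- phi_cw
      dir <- -1
    } else {
      phi_ccw <- solve_arc(pos, heading, r, target, dir = 1)
      if (phi_ccw < phi_cw) {
        phi <- phi_ccw; dir <- 1
      } else {
        phi <- phi_cw; dir <- -1
      }
    }
    if (phi > 1e-9) {
      a <- seg_arc(pos, heading, r, phi, dir = dir)
      segs <- c(segs, list(a))
      e <- seg_end(a)
      pos <- e$pos; heading <- e$heading
    }
    s <- seg_straight(pos, target)
    if (s$len > 1e-9) segs <- c(segs, list(s))
    list(segs = segs, end = seg_end(s))
  }

  # the flight begins at the turnaround waypoint behind the start corner so
  # that every repetition, including the first, enters the start region on
  # the same approach; the pre-entry stretch is the "starting period" that
  # repetition segmentation excludes
  segs <- list(seg_straight(behind, start))
  pos <- start
  heading <- u0
  for (rep_i in seq_len(n_repetitions)) {
    # corrective steer onto the feeder (exact no-op on the first repetition)
    st <- steer_to(pos, heading, feeder)
    segs <- c(segs, st$segs)
    pos <- st$end$pos; heading <- st$end$heading
    for (lobe in 1:3) {
      beyond <- pos + leg_beyond_m * unit_vec(heading)
      s <- seg_straight(pos, beyond)
      segs <- c(segs, list(s))
      pos <- beyond
      st <- steer_to(pos, heading, feeder, direction = "cw")
      segs <- c(segs, st$segs)
      pos <- st$end$pos; heading <- st$end$heading
    }
    # return to the start corner via the turnaround waypoint behind it
    st <- steer_to(pos, heading, behind)
    segs <- c(segs, st$segs)
    pos <- st$end$pos; heading <- st$end$heading
    st <- steer_to(pos, heading, start)
    segs <- c(segs, st$segs)
    pos <- st$end$pos; heading <- st$end$heading
  }

  lens <- vapply(segs, function(s) s$len, numeric(1))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  dt <- 1 / sample_hz
  t <- seq(0, total / speed_m_s, by = dt)
  s_along <- t * speed_m_s
  seg_idx <- pmin(findInterval(s_along, cum, rightmost.closed = TRUE),
                  length(segs))
  n <- length(t)
  xs <- numeric(n); ys <- numeric(n); hs <- numeric(n)
  for (i in seq_len(n)) {
    k <- seg_idx[i]
    at <- seg_at(segs[[k]], s_along[i] - cum[k])
    xs[i] <- at$pos[1]; ys[i] <- at$pos[2]; hs[i] <- at$heading
  }
  hs <- wrap_angle(hs)
  hu <- unwrap_angle(hs)
  yaw_rate <- c(diff(hu), 0) / dt
  yaw_rate[n] <- yaw_rate[n - 1]
  tel <- telemetry_track(t, xs, ys, rep(altitude_m, n), hs, yaw_rate,
                         rep(speed_m_s, n))

  # repetition bounds: entries into the start region while on the initial
  # bearing (the definition used by segment_repetitions)
  d <- sqrt((xs - start[1])^2 + (ys - start[2])^2)
  state <- d <= start_region_radius_m & abs(angle_diff(hs, u0)) < pi / 2
  entries <- which(state & !c(FALSE, state[-n]))
  entry_t <- t[entries]
  if (length(entry_t) >= 2) {
    bounds <- cbind(start_s = entry_t[-length(entry_t)],
                    end_s = entry_t[-1])
  } else {
    bounds <- cbind(start_s = 0, end_s = t[n])
  }
  list(telemetry = tel, repetition_bounds = bounds)
}

#' Generate yaw-modulated inhomogeneous Poisson spike trains
#'
#' Per-unit spike trains with instantaneous rate
#' `lambda(t) = baseline + rate_gain * |yaw_rate(t - lag_s)|`, simulated by
#' Lewis-Shedler thinning of a homogeneous Poisson process at the rate
#' ceiling, followed by forward deletion of spikes violating the refractory
#' period. Deterministic for a fixed seed.
#'
#' @param telemetry a [telemetry_track] providing `|yaw rate|`.
#' @param n_units number of units (default 3).
#' @param baseline_rate_hz baseline firing rate (default 10 Hz).
#' @param rate_gain rate gain in Hz per rad/s of yaw speed (default 25).
#' @param lag_s latency of the rate modulation behind the yaw signal
#'   (default 0.7 s).
#' @param refractory_s enforced absolute refractory period (default 4 ms).
#' @param relative_refractory_s recovery time constant of a relative
#'   refractory period (default 3 ms): a spike at gap `g` after its
#'   predecessor survives with probability
#'   `1 - exp(-(g - refractory_s) / relative_refractory_s)`, so the ISI
#'   distribution is depleted just above the absolute dead time, as in real
#'   single-unit ISI histograms (single mode far above the dead time, very
#'   few intervals below ~5 ms). `0` disables it.
#' @param time_resolution_s spike times are snapped to this grid (default
#'   one 20 kHz recording sample) before the refractory period is enforced,
#'   so refractoriness holds exactly at recording resolution; `0` keeps
#'   continuous times.
#' @param seed RNG seed.
#' @return object of class `ground_truth`: list with `unit_spike_times`
#'   (list of numeric vectors), `injected_lag_s`, `rate_gain`,
#'   `baseline_rate_hz`, `refractory_s`, `seed`.
#' @export
gen_spike_trains <- function(telemetry, n_units = 3, baseline_rate_hz = 10,
                             rate_gain = 25, lag_s = 0.7,
                             refractory_s = 0.004,
                             relative_refractory_s = 0.003,
                             time_resolution_s = 5e-5, seed = 1) {
  if (baseline_rate_hz < 0 || lag_s < 0 || refractory_s < 0 ||
      rate_gain < 0) {
    stop("rates, lag and refractory period must be non-negative")
  }
  t_end <- telemetry$t_s[nrow(telemetry)]
  if (t_end <= lag_s) stop("telemetry shorter than the injected lag")
  abs_yr <- abs(telemetry$yaw_rate_rad_s)
  lambda_fun <- function(t) {
    baseline_rate_hz + rate_gain *
      stats::approx(telemetry$t_s, abs_yr, xout = pmax(t - lag_s, 0),
                    rule = 2)$y
  }
  lambda_max <- baseline_rate_hz + rate_gain * max(abs_yr)
  set.seed(seed)
  unit_spike_times <- lapply(seq_len(n_units), function(u) {
    if (lambda_max == 0) return(numeric(0))
    n_cand <- stats::rpois(1, lambda_max * t_end)
    if (n_cand == 0) return(numeric(0))
    cand <- sort(stats::runif(n_cand, 0, t_end))
    keep <- stats::runif(n_cand) < lambda_fun(cand) / lambda_max
    st <- cand[keep]
    if (time_resolution_s > 0) {
      st <- unique(round(st / time_resolution_s) * time_resolution_s)
    }
    enforce_refractory(st, refractory_s, relative_refractory_s)
  })
  structure(
    list(unit_spike_times = unit_spike_times,
         injected_lag_s = lag_s, rate_gain = rate_gain,
         baseline_rate_hz = baseline_rate_hz, refractory_s = refractory_s,
         seed = seed),
    class = "ground_truth"
  )
}

# forward deletion: walk the train and drop spikes closer than refractory_s
# to the last kept spike; with relative_s > 0, spikes just above the
# absolute dead time are additionally thinned by the recovery hazard
enforce_refractory <- function(times, refractory_s, relative_s = 0) {
  if (length(times) < 2 || (refractory_s <= 0 && relative_s <= 0)) {
    return(times)
  }
  u <- if (relative_s > 0) stats::runif(length(times)) else NULL
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    gap <- times[i] - last
    if (gap < refractory_s) next
    if (relative_s > 0 && u[i] > 1 - exp(-(gap - refractory_s) / relative_s)) {
      next
    }
    keep[i] <- TRUE
    last <- times[i]
  }
  times[keep]
}

#' Noise model for synthetic recordings
#'
#' Describes the copter's electrical interference as seen by the electrodes:
#' a common-mode component (rotor/motor harmonics plus band-limited
#' broadband noise and occasional switching impulses) whose amplitude
#' follows the copter's speed, and independent per-channel noise. All
#' components are band-limited to the hardware filter band.
#'
#' @param common_mode_harmonics matrix-like with columns `freq_hz`,
#'   `amplitude` (normalized units, where a spike trough is ~1).
#' @param common_broadband_sd sd of the band-limited broadband common-mode
#'   component.
#' @param impulse_rate_hz rate of transient common-mode impulses.
#' @param impulse_amplitude amplitude of the impulses.
#' @param independent_noise_sd per-channel independent noise sd (length 1
#'   or 2).
#' @param band_hz passband `c(low, high)` in Hz (default 300-10000,
#'   the hardware bandpass).
#' @param envelope_range amplitude envelope `c(min, max)` tied to copter
#'   speed: the common-mode amplitude scales linearly from min (standstill)
#'   to max (top speed).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(common_mode_harmonics = cbind(
                          freq_hz = c(400, 800, 1600, 3200),
                          amplitude = c(1.2, 0.9, 0.6, 0.35)),
                        common_broadband_sd = 0.6,
                        impulse_rate_hz = 0.2,
                        impulse_amplitude = 4,
                        independent_noise_sd = 0.05,
                        band_hz = c(300, 10000),
                        envelope_range = c(0.6, 1.4)) {
  h <- as.matrix(common_mode_harmonics)
  if (nrow(h) > 0 && any(h[, 2] < 0)) stop("harmonic amplitudes must be >= 0")
  if (band_hz[1] >= band_hz[2] || band_hz[1] <= 0) {
    stop("band must satisfy 0 < low < high")
  }
  structure(
    list(common_mode_harmonics = h,
         common_broadband_sd = common_broadband_sd,
         impulse_rate_hz = impulse_rate_hz,
         impulse_amplitude = impulse_amplitude,
         independent_noise_sd = rep(independent_noise_sd, length.out = 2),
         band_hz = band_hz,
         envelope_range = envelope_range),
    class = "noise_model"
  )
}

# zero-phase FFT band mask
bandpass_fft <- function(x, sample_hz, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) * sample_hz / n
  f <- pmin(f, sample_hz - f)  # two-sided frequency axis
  X <- stats::fft(x)
  X[f < band[1] | f > band[2]] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Synthesize a two-channel recording from ground truth
#'
#' Builds `channel_i = gain_i * common_noise + spike_i + independent_i`,
#' with each unit's template injected at its ground-truth spike times with
#' opposite polarity on the two channels (half amplitude each), so that the
#' gain-matched differential cancels the common-mode noise and preserves the
#' spikes. The result is quantized to 16-bit integer counts. If more than 1%
#' of samples clip, a warning is raised.
#'
#' @param ground_truth a `ground_truth` from [gen_spike_trains()] (or a bare
#'   list of per-unit spike-time vectors).
#' @param templates list of unit templates (see [default_templates()]),
#'   trough-normalized to -1.
#' @param noise a [noise_model].
#' @param channel_gains common-mode gains of the two channels (default
#'   `c(2, 1)`, emulating the impedance mismatch).
#' @param duration_s recording length; defaults to the telemetry span when
#'   given, else to the last spike plus 1 s.
#' @param telemetry optional [telemetry_track] driving the common-mode
#'   amplitude envelope (faster flight, more noise).
#' @param sample_hz sampling rate (default 20000).
#' @param counts_per_unit quantization scale: normalized amplitude 1.0 in
#'   16-bit counts (default 1500).
#' @param attenuation_episodes optional data.frame with `start_s`, `end_s`,
#'   `factor`: spikes inside an episode are injected with their amplitude
#'   scaled by `factor` (shape intact), emulating episodes in which spike
#'   amplitude drops relative to the local noise floor.
#' @param seed RNG seed.
#' @return a [raw_recording] with integer count samples.
#' @export
gen_recording <- function(ground_truth, templates, noise = noise_model(),
                          channel_gains = c(2, 1), duration_s = NULL,
                          telemetry = NULL, sample_hz = 20000,
                          counts_per_unit = 1000,
                          attenuation_episodes = NULL, seed = 1) {
  spikes <- if (inherits(ground_truth, "ground_truth")) {
    ground_truth$unit_spike_times
  } else ground_truth
  if (length(templates) != length(spikes)) {
    stop("need one template per unit")
  }
  if (is.null(duration_s)) {
    duration_s <- if (!is.null(telemetry)) {
      telemetry$t_s[nrow(telemetry)]
    } else {
      max(c(unlist(spikes), 0)) + 1
    }
  }
  n <- as.integer(round(duration_s * sample_hz))
  set.seed(seed)

  # common-mode noise: harmonics + band-limited broadband + impulses
  tt <- (seq_len(n) - 1) / sample_hz
  common <- numeric(n)
  h <- noise$common_mode_harmonics
  if (nrow(h) > 0) {
    phases <- stats::runif(nrow(h), 0, 2 * pi)
    for (j in seq_len(nrow(h))) {
      common <- common + h[j, 2] * sin(2 * pi * h[j, 1] * tt + phases[j])
    }
  }
  if (noise$common_broadband_sd > 0) {
    bb <- stats::rnorm(n, sd = noise$common_broadband_sd)
    common <- common + bandpass_fft(bb, sample_hz, noise$band_hz)
  }
  if (noise$impulse_rate_hz > 0) {
    n_imp <- stats::rpois(1, noise$impulse_rate_hz * duration_s)
    if (n_imp > 0) {
      imp_t <- stats::runif(n_imp, 0, duration_s)
      kernel <- noise$impulse_amplitude *
        exp(-(0:round(0.005 * sample_hz)) / (0.001 * sample_hz))
      imp <- numeric(n)
      for (ti in imp_t) {
        i0 <- floor(ti * sample_hz) + 1
        idx <- i0:min(n, i0 + length(kernel) - 1)
        imp[idx] <- imp[idx] + kernel[seq_along(idx)]
      }
      common <- common + bandpass_fft(imp, sample_hz, noise$band_hz)
    }
  }
  # amplitude envelope tied to copter speed (acceleration/fast segments are
  # noisier)
  if (!is.null(telemetry)) {
    sp <- stats::approx(telemetry$t_s, telemetry$speed_m_s, xout = tt,
                        rule = 2)$y
    top <- max(telemetry$speed_m_s, 1e-9)
    env <- noise$envelope_range[1] +
      (noise$envelope_range[2] - noise$envelope_range[1]) * sp / top
    common <- common * env
  }

  # spike signal: opposite polarity across channels, half amplitude each
  spike_a <- numeric(n)
  w <- length(templates[[1]])
  half <- (w - 1) %/% 2
  for (u in seq_along(spikes)) {
    tpl <- templates[[u]]
    for (ts in spikes[[u]]) {
      i0 <- round(ts * sample_hz) + 1
      lo <- i0 - half
      hi <- i0 + half
      if (lo < 1 || hi > n) next
      fac <- 1
      if (!is.null(attenuation_episodes)) {
        inep <- which(ts >= attenuation_episodes$start_s &
                      ts < attenuation_episodes$end_s)
        if (length(inep)) fac <- attenuation_episodes$factor[inep[1]]
      }
      spike_a[lo:hi] <- spike_a[lo:hi] + 0.5 * fac * tpl
    }
  }

  ind_a <- bandpass_fft(stats::rnorm(n, sd = noise$independent_noise_sd[1]),
                        sample_hz, noise$band_hz)
  ind_b <- bandpass_fft(stats::rnorm(n, sd = noise$independent_noise_sd[2]),
                        sample_hz, noise$band_hz)
  ch_a <- channel_gains[1] * common + spike_a + ind_a
  ch_b <- channel_gains[2] * common - spike_a + ind_b

  qa <- round(ch_a * counts_per_unit)
  qb <- round(ch_b * counts_per_unit)
  clip_frac <- mean(c(abs(qa), abs(qb)) > 32767)
  if (clip_frac > 0.01) {
    warning(sprintf("%.1f%% of samples clipped at the 16-bit range",
                    100 * clip_frac))
  }
  raw_recording(clip_int16(qa), clip_int16(qb), sample_rate_hz = sample_hz,
                start_time_s = 0)
}

#' Generate a synthetic terrain model
#'
#' A smooth random height field (white noise blurred by repeated moving
#' averages), or a flat field, with a boolean field mask derived from a
#' polygon. Deterministic for a fixed seed.
#'
#' @param extent_m grid extent `c(width, height)` in meters (scalar =
#'   square).
#' @param cell_m cell size in meters.
#' @param field_polygon two-column matrix of polygon vertices (x, y) in
#'   meters; default is a centered rectangle covering 60% of the extent.
#' @param origin_xy_m lower-left corner coordinates.
#' @param relief_m peak-to-peak scale of the height field; 0 gives a flat
#'   terrain.
#' @param seed RNG seed.
#' @return a [terrain_model].
#' @export
gen_terrain <- function(extent_m = c(200, 200), cell_m = 2,
                        field_polygon = NULL, origin_xy_m = c(-50, -25),
                        relief_m = 2, seed = 1) {
  extent_m <- rep(extent_m, length.out = 2)
  if (any(extent_m <= 0) || cell_m <= 0) stop("extent and cell must be positive")
  nc <- as.integer(ceiling(extent_m[1] / cell_m))
  nr <- as.integer(ceiling(extent_m[2] / cell_m))
  if (relief_m > 0) {
    set.seed(seed)
    h <- matrix(stats::rnorm(nr * nc), nr, nc)
    for (k in 1:4) {
      h <- blur3(h)
    }
    h <- h - min(h)
    h <- h / max(h) * relief_m
  } else {
    h <- matrix(0, nr, nc)
  }
  if (is.null(field_polygon)) {
    cx <- origin_xy_m[1] + extent_m[1] / 2
    cy <- origin_xy_m[2] + extent_m[2] / 2
    wx <- 0.3 * extent_m[1]
    wy <- 0.3 * extent_m[2]
    field_polygon <- cbind(c(cx - wx, cx + wx, cx + wx, cx - wx),
                           c(cy - wy, cy - wy, cy + wy, cy + wy))
  }
  field_polygon <- as.matrix(field_polygon)
  if (nrow(field_polygon) < 3 ||
      abs(polygon_area(field_polygon)) < 1e-9) {
    stop("degenerate field polygon")
  }
  # mask from cell centers (row 1 = north)
  xc <- origin_xy_m[1] + (seq_len(nc) - 0.5) * cell_m
  yc <- origin_xy_m[2] + (nr - seq_len(nr) + 0.5) * cell_m
  mask <- outer(seq_len(nr), seq_len(nc), function(r, c) {
    point_in_polygon(xc[c], yc[r], field_polygon)
  })
  terrain_model(h, origin_xy_m, cell_m, mask)
}

blur3 <- function(m) {
  p <- rbind(m[1, ], m, m[nrow(m), ])
  p <- cbind(p[, 1], p, p[, ncol(p)])
  nr <- nrow(m); nc <- ncol(m)
  (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
   p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] + p[2:(nr + 1), 3:(nc + 2)] +
   p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(nrow(poly), seq_len(nrow(poly) - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# even-odd rule, vectorized over query points
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
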