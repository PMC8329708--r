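#' Two-channel extracellular recording
#'
#' Container for the two synchronized monopolar channels recorded against a
#' shared ground. Samples may be raw 16-bit counts (as read from disk) or
#' normalized floats (after preprocessing).
#'
#' @param channel_a,channel_b numeric sample vectors of equal length.
#' @param sample_rate_hz sampling rate in Hz (20000 for the field hardware).
#' @param start_time_s start time of sample 1 on the telemetry clock, seconds.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(channel_a, channel_b, sample_rate_hz = 20000,
                          start_time_s = 0) {
  if (length(channel_a) != length(channel_b)) {
    stop("channel lengths differ: ", length(channel_a), " vs ", length(channel_b))
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive")
  }
  structure(
    list(channel_a = as.numeric(channel_a),
         channel_b = as.numeric(channel_b),
         sample_rate_hz = sample_rate_hz,
         start_time_s = start_time_s),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: 2 x %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              length(x$channel_a), x$sample_rate_hz,
              length(x$channel_a) / x$sample_rate_hz, x$start_time_s))
  invisible(x)
}

#' Sample times of a recording
#'
#' @param rec a [raw_recording].
#' @return numeric vector of per-sample times in seconds (telemetry clock).
#' @export
recording_times <- function(rec) {
  rec$start_time_s + (seq_along(rec$channel_a) - 1) / rec$sample_rate_hz
}

#' Copter telemetry track
#'
#' Parallel arrays of pose and kinematics at a nominal 100 Hz: time, local
#' metric east/north position, altitude, yaw (radians, ENU, counterclockwise
#' positive), yaw rate, and ground speed.
#'
#' @param t_s,x_m,y_m,alt_m,yaw_rad,yaw_rate_rad_s,speed_m_s equal-length
#'   numeric vectors; `t_s` must be strictly increasing.
#' @return an object of class `telemetry_track`.
#' @export
telemetry_track <- function(t_s, x_m, y_m, alt_m, yaw_rad, yaw_rate_rad_s,
                            speed_m_s) {
  n <- length(t_s)
  lens <- c(length(x_m), length(y_m), length(alt_m), length(yaw_rad),
            length(yaw_rate_rad_s), length(speed_m_s))
  if (any(lens != n)) stop("telemetry columns must have equal length")
  if (n >= 2 && any(diff(t_s) <= 0)) {
    stop("telemetry time must be strictly increasing")
  }
  structure(
    data.frame(t_s = t_s, x_m = x_m, y_m = y_m, alt_m = alt_m,
               yaw_rad = yaw_rad, yaw_rate_rad_s = yaw_rate_rad_s,
               speed_m_s = speed_m_s),
    class = c("telemetry_track", "data.frame")
  )
}

#' Write / read telemetry CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `t_s,x_m,y_m,alt_m,yaw_rad,yaw_rate_rad_s,speed_m_s`, '.' decimal and
#' comma separator. Yaw is stored in radians (ENU, CCW positive), noted in a
#' leading comment line.
#'
#' @param tel a [telemetry_track].
#' @param path file path.
#' @return `path` invisibly (write); a [telemetry_track] (read).
#' @export
write_telemetry <- function(tel, path) {
  stopifnot(inherits(tel, "telemetry_track"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# yaw_rad: ENU frame, counterclockwise positive, radians", con)
  utils::write.table(as.data.frame(tel), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_telemetry
#' @export
read_telemetry <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  needed <- c("t_s", "x_m", "y_m", "alt_m", "yaw_rad", "yaw_rate_rad_s",
              "speed_m_s")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("telemetry CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  telemetry_track(df$t_s, df$x_m, df$y_m, df$alt_m, df$yaw_rad,
                  df$yaw_rate_rad_s, df$speed_m_s)
}

#' Align a recording with telemetry
#'
#' Builds a session that maps recording time onto the telemetry stream via a
#' constant clock offset (the GPS-timestamp merge of the field system is
#' modeled as this single offset). The aligned time ranges must overlap.
#'
#' @param recording a [raw_recording].
#' @param telemetry a [telemetry_track].
#' @param clock_offset_s seconds added to recording time to map it onto
#'   telemetry time.
#' @return an object of class `bee_session`.
#' @export
align <- function(recording, telemetry, clock_offset_s = 0) {
  stopifnot(inherits(recording, "raw_recording"),
            inherits(telemetry, "telemetry_track"))
  if (!is.finite(clock_offset_s)) stop("clock_offset_s must be finite")
  rec_t0 <- recording$start_time_s + clock_offset_s
  rec_t1 <- rec_t0 + length(recording$channel_a) / recording$sample_rate_hz
  tel_t0 <- telemetry$t_s[1]
  tel_t1 <- telemetry$t_s[nrow(telemetry)]
  if (min(rec_t1, tel_t1) <= max(rec_t0, tel_t0)) {
    stop("recording and telemetry do not overlap in time after offset")
  }
  structure(
    list(recording = recording, telemetry = telemetry,
         clock_offset_s = clock_offset_s),
    class = "bee_session"
  )
}

#' Interpolated telemetry state at given times
#'
#' Linearly interpolates position, altitude, yaw rate and speed at arbitrary
#' telemetry-clock times; yaw is interpolated on the circle (shortest arc)
#' by unwrapping before interpolation. Times outside the telemetry range are
#' clamped to the nearest sample.
#'
#' @param session a `bee_session` from [align()], or a [telemetry_track].
#' @param t_s times in seconds. For a session these are recording times and
#'   the session's clock offset is applied; for a bare track they are
#'   telemetry times.
#' @return a data.frame with columns `t_s, x_m, y_m, alt_m, yaw_rad,
#'   yaw_rate_rad_s, speed_m_s`, one row per query time.
#' @export
telemetry_at <- function(session, t_s) {
  if (inherits(session, "bee_session")) {
    tel <- session$telemetry
    tq <- t_s + session$clock_offset_s
  } else if (inherits(session, "telemetry_track")) {
    tel <- session
    tq <- t_s
  } else {
    stop("session must be a bee_session or telemetry_track")
  }
  li <- function(v) stats::approx(tel$t_s, v, xout = tq, rule = 2)$y
  yaw_unwrapped <- unwrap_angle(tel$yaw_rad)
  data.frame(
    t_s = tq,
    x_m = li(tel$x_m),
    y_m = li(tel$y_m),
    alt_m = li(tel$alt_m),
    yaw_rad = wrap_angle(stats::approx(tel$t_s, yaw_unwrapped, xout = tq,
                                       rule = 2)$y),
    yaw_rate_rad_s = li(tel$yaw_rate_rad_s),
    speed_m_s = li(tel$speed_m_s)
  )
}

# cumulative unwrap: removes 2*pi jumps so linear interpolation follows the
# shortest arc between consecutive samples
unwrap_angle <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  corr <- cumsum(c(0, -2 * pi * round(d / (2 * pi))))
  theta + corr
}

wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # map -pi to +pi for a stable convention
  w[w <= -pi + .Machine$double.eps] <- pi * sign(pi)
  w
}
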