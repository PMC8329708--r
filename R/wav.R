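#' Read a 2-channel 16-bit PCM WAV recording
#'
#' Parses a RIFF/WAVE file containing exactly two channels of 16-bit signed
#' PCM samples, the container used for copter-borne extracellular
#' recordings (20 kHz by convention). Sample values are returned as raw
#' integer counts in \code{[-32768, 32767]}.
#'
#' @param path path to a \code{.wav} file.
#' @param start_time_s recording start time in seconds on the telemetry
#'   clock (the container itself carries no timestamp).
#' @return a [raw_recording] object.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, start_time_s = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  sample_rate <- NULL
  n_channels <- NULL
  bits <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "integer", size / 2, size = 2,
                          signed = TRUE, endian = "little")
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(data_raw) && !is.null(sample_rate)) break
  }
  if (is.null(sample_rate) || is.null(data_raw)) {
    stop("malformed WAV: missing fmt or data chunk")
  }
  if (n_channels != 2L) {
    stop("format error: expected 2 channels, found ", n_channels)
  }
  if (bits != 16L) {
    stop("format error: expected 16-bit PCM, found ", bits, "-bit")
  }
  # interleaved LRLR...
  a <- data_raw[seq(1, length(data_raw), by = 2)]
  b <- data_raw[seq(2, length(data_raw), by = 2)]
  raw_recording(a, b, sample_rate_hz = sample_rate, start_time_s = start_time_s)
}

#' Write a recording as 2-channel 16-bit PCM WAV
#'
#' Inverse of [read_recording()]; the write/read round trip is bit-exact on
#' sample values. Non-integer sample values are rounded and clipped to the
#' 16-bit range.
#'
#' @param rec a [raw_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  a <- clip_int16(round(rec$channel_a))
  b <- clip_int16(round(rec$channel_b))
  n <- length(a)
  interleaved <- integer(2L * n)
  interleaved[seq(1, 2 * n, by = 2)] <- a
  interleaved[seq(2, 2 * n, by = 2)] <- b
  data_bytes <- 2L * 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(2L, con, size = 2, endian = "little")   # channels
  writeBin(as.integer(rec$sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate_hz * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(interleaved, con, size = 2, endian = "little")
  invisible(path)
}

clip_int16 <- function(x) as.integer(pmin(32767, pmax(-32768, x)))
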