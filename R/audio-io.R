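# Minimal mono WAV I/O (PCM 16-bit and IEEE float32).
#
# No audio package is assumed; the front end only needs raw samples and a
# sampling rate. PCM samples are kept on their raw integer scale, matching
# the convention that the envelope peak-prominence threshold (the "Hilbert
# unit") is expressed in waveform sample units.

#' Construct an audio signal
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in samples/second.
#' @return an `audio_signal` object (list with `samples`, `rate`).
#' @export
audio_signal <- function(samples, rate) {
  rate <- as.numeric(rate)
  stopifnot_scalar(rate, "rate")
  if (rate <= 0) stop("`rate` must be > 0")
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Read a mono channel from a WAV file
#'
#' Supports PCM 16-bit and IEEE float32 encodings. Multi-channel files are
#' de-interleaved and one channel is selected (field recordings from
#' microphone arrays typically use the first channel).
#'
#' @param path WAV file path.
#' @param channel 1-based channel to keep.
#' @return an [audio_signal()]; PCM samples stay on the integer scale.
#' @export
read_wav <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        byterate = readBin(con, "integer", 1, size = 4, endian = "little"),
        align = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits = readBin(con, "integer", 1, size = 2, endian = "little"))
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)
  if (fmt$code == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little")
  } else if (fmt$code == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                 endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                 fmt$code, fmt$bits))
  }
  if (channel < 1 || channel > fmt$channels) stop("channel out of range")
  x <- x[seq(channel, length(x), by = fmt$channels)]
  audio_signal(x, fmt$rate)
}

#' Write an audio signal to a mono PCM 16-bit WAV file
#' @param signal an [audio_signal()]; samples are clamped to the int16 range.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_wav <- function(signal, path) {
  x <- as.integer(pmin(pmax(round(signal$samples), -32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")  # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")  # mono
  writeBin(as.integer(signal$rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")
  writeBin(as.integer(16), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}
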