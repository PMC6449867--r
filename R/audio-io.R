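#' Audio recording container
#'
#' A uniformly sampled single-channel sound recording. Samples are stored as
#' a numeric vector in arbitrary units (WAV input is scaled to `[-1, 1]`).
#'
#' @param samples numeric vector of amplitudes; must be finite and non-empty.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param start_time offset of the first sample in seconds (default 0).
#' @return an object of class `audio_recording` with fields `samples`,
#'   `sample_rate` and `start_time`.
#' @export
audio_recording <- function(samples, sample_rate, start_time = 0) {
  if (!is.numeric(samples) || length(samples) < 1L)
    abort_argument("`samples` must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    abort_argument("`samples` must contain finite values only")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    abort_argument("`sample_rate` must be a single positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         start_time = as.numeric(start_time)),
    class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$sample_rate, duration(x)))
  invisible(x)
}

#' Recording duration in seconds
#' @param x an `audio_recording` or `imu_recording`.
#' @return duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.audio_recording <- function(x) length(x$samples) / x$sample_rate

#' Read a mono PCM WAV file
#'
#' Parses a RIFF/WAVE file containing a single channel of 16- or 32-bit
#' integer PCM or 32-bit IEEE float samples. Integer samples are scaled to
#' `[-1, 1]`; the sample rate is taken from the header.
#'
#' @param path path to the WAV file.
#' @return an [audio_recording()].
#' @export
read_audio <- function(path) {
  if (!file.exists(path))
    abort_format(sprintf("audio file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    abort_format(sprintf("not a RIFF/WAVE file: %s", path))
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    abort_format(sprintf("not a RIFF/WAVE file: %s", path))

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L)
      abort_format(sprintf("no data chunk in WAV file: %s", path))
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        n_channels   = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        sample_rate  = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        byte_rate    = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        block_align  = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        bits         = readBin(con, "integer", 1L, size = 2L, endian = "little"))
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(fmt))
        abort_format(sprintf("WAV data chunk precedes fmt chunk: %s", path))
      if (fmt$n_channels != 1L)
        abort_format(sprintf("expected mono audio, found %d channels: %s",
                             fmt$n_channels, path))
      n <- size %/% (fmt$bits %/% 8L)
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        raw <- readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "little")
        samples <- raw / 32768
      } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
        raw <- readBin(con, "integer", n, size = 4L, endian = "little")
        samples <- raw / 2147483648
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", n, size = 4L, endian = "little")
      } else {
        abort_format(sprintf("unsupported WAV encoding (format %d, %d bit): %s",
                             fmt$audio_format, fmt$bits, path))
      }
      return(audio_recording(samples, fmt$sample_rate))
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip unknown chunk (padded)
    }
  }
}

#' Write a mono PCM WAV file
#'
#' @param audio an [audio_recording()]; samples outside `[-1, 1]` are clipped.
#' @param path output path.
#' @param bits sample width, 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_audio <- function(audio, path, bits = 16L) {
  stopifnot(inherits(audio, "audio_recording"))
  if (!bits %in% c(16L, 32L))
    abort_argument("`bits` must be 16 or 32")
  x <- pmax(pmin(audio$samples, 1), -1)
  n <- length(x)
  bytes <- n * (bits %/% 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(round(audio$sample_rate)), con, size = 4L, endian = "little")
  writeBin(as.integer(round(audio$sample_rate) * (bits %/% 8L)), con, size = 4L, endian = "little")
  writeBin(as.integer(bits %/% 8L), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(bytes), con, size = 4L, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(pmax(pmin(round(x * 32767), 32767), -32768)), con,
             size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Resample an audio recording to a target rate
#'
#' All filter banks in the package are designed against a fixed 5 kHz
#' reference rate; recordings at other rates are resampled (polyphase,
#' via [signal::resample()]) before any DSP.
#'
#' @param audio an [audio_recording()].
#' @param rate target sample rate in Hz (default 5000).
#' @return an [audio_recording()] at `rate` Hz.
#' @export
resample_audio <- function(audio, rate = 5000) {
  stopifnot(inherits(audio, "audio_recording"))
  if (audio$sample_rate == rate) return(audio)
  g <- gcd(round(rate), round(audio$sample_rate))
  y <- signal::resample(audio$samples, round(rate) / g, round(audio$sample_rate) / g)
  audio_recording(as.numeric(y), rate, audio$start_time)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
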