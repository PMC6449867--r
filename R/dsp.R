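## Core DSP: linear-phase FIR filtering, short-time Fourier analysis with
## overlap-add reconstruction, spectral subtraction and short-term RMS
## envelope. These are the building blocks of the respiratory (Figure-2
## style) and cardiac (Figure-3 style) processing chains.

## Hamming-windowed linear-phase FIR design; order is chosen so the
## transition band stays comfortably inside the gap between probe tones
## and band edges (~3.3/order * fs wide), stopband >= ~50 dB (Hamming).
design_fir <- function(fs, low = NULL, high = NULL, order = NULL) {
  if (is.null(order)) order <- min(320L, max(128L, as.integer(round(fs / 16))))
  if (order %% 2L == 1L) order <- order + 1L  # even order -> odd, symmetric taps
  nyq <- fs / 2
  if (!is.null(low) && !is.null(high)) {
    if (high >= nyq) abort_argument(sprintf(
      "sample rate %g Hz too low for passband up to %g Hz", fs, high))
    b <- signal::fir1(order, c(low, high) / nyq, type = "pass")
  } else if (!is.null(high)) {
    b <- signal::fir1(order, high / nyq, type = "low")
  } else {
    b <- signal::fir1(order, low / nyq, type = "high")
  }
  as.numeric(b)
}

## Apply a symmetric FIR with group-delay compensation (net zero phase).
## FFT overlap-add (compiled) keeps memory bounded on multi-hour signals.
apply_fir <- function(x, b) {
  as.numeric(fir_filter_cpp(as.numeric(x), as.numeric(b)))
}

#' Band-pass filter for the breathing band
#'
#' Isolates breath sound with a linear-phase FIR band-pass (default
#' 200--2000 Hz), group delay compensated so events keep their timing.
#'
#' @param audio an [audio_recording()] with `sample_rate >= 2 * band[2]`.
#' @param band numeric length-2, passband edges in Hz.
#' @param order FIR order; default scales with the sample rate.
#' @return a filtered [audio_recording()].
#' @export
bandpass_breath <- function(audio, band = c(200, 2000), order = NULL) {
  stopifnot(inherits(audio, "audio_recording"))
  if (audio$sample_rate < 2 * band[2])
    abort_argument(sprintf(
      "sample rate %g Hz cannot represent the %g Hz band edge",
      audio$sample_rate, band[2]))
  b <- design_fir(audio$sample_rate, band[1], band[2])
  audio_recording(apply_fir(audio$samples, b), audio$sample_rate, audio$start_time)
}

## --- STFT helpers ----------------------------------------------------------

## Periodic Hann: with hop = frame/2 adjacent windows sum to exactly 1,
## so analysis-windowed overlap-add is an identity when spectra are not
## modified.
hann_periodic <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / n))

## Frame a signal into a matrix (no padding, no window) -- used for noise
## template estimation. Fast contiguous reshape when hop = frame/2.
frame_signal <- function(x, frame, hop) {
  if (length(x) < frame) abort_argument("signal shorter than one frame")
  if (hop * 2L == frame) {
    cols <- function(off) {
      m <- (length(x) - off) %/% frame
      if (m < 1L) return(NULL)
      matrix(x[(off + 1L):(off + m * frame)], nrow = frame)
    }
    return(cbind(cols(0L), cols(hop)))
  }
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  matrix(x[outer(0:(frame - 1L), starts, `+`)], nrow = frame)
}

#' Estimate a stationary-noise magnitude template
#'
#' Ranks STFT frames by energy and averages the magnitude spectra of the
#' quietest fraction, yielding a background-noise template that excludes
#' breath bursts and other transient energy.
#'
#' @param audio an [audio_recording()] of at least 30 s.
#' @param frame FFT frame length in samples (default 1024).
#' @param hop hop between frames (default `frame / 2`).
#' @param quietest_frac fraction of lowest-energy frames averaged (default 0.1).
#' @return numeric vector of length `frame`: the mean magnitude spectrum of
#'   the quiet frames (Hann-windowed analysis, matching [spectral_subtract()]).
#' @export
estimate_noise_template <- function(audio, frame = 1024L, hop = frame %/% 2L,
                                    quietest_frac = 0.1) {
  stopifnot(inherits(audio, "audio_recording"))
  if (duration(audio) < 30)
    abort_argument("noise template estimation needs at least 30 s of audio")
  w <- hann_periodic(frame)
  frames <- frame_signal(audio$samples, frame, hop) * w
  energy <- colSums(frames^2)
  k <- max(1L, floor(quietest_frac * ncol(frames)))
  quiet <- frames[, order(energy)[seq_len(k)], drop = FALSE]
  rowMeans(Mod(stats::mvfft(quiet)))
}

#' Spectral subtraction of a noise template
#'
#' Short-time spectral subtraction: each Hann-windowed frame's magnitude is
#' reduced by `alpha` times the noise template (floored at `floor_frac`
#' times the original magnitude), the phase is kept, and frames are
#' overlap-added back to a signal of the original length. `alpha > 1`
#' (over-subtraction) compensates for the spread of noise magnitudes
#' around their mean; `alpha = 1, template = 0` is an exact identity.
#'
#' @param audio an [audio_recording()].
#' @param template magnitude spectrum of length `frame`
#'   (see [estimate_noise_template()]).
#' @param frame,hop STFT geometry; `hop` must be `frame / 2` for exact
#'   overlap-add reconstruction.
#' @param alpha over-subtraction factor (default 2).
#' @param floor_frac spectral floor as a fraction of the frame magnitude
#'   (default 0.01).
#' @return a denoised [audio_recording()], same length as the input.
#' @export
spectral_subtract <- function(audio, template, frame = 1024L,
                              hop = frame %/% 2L, alpha = 2, floor_frac = 0.01) {
  stopifnot(inherits(audio, "audio_recording"))
  if (length(template) != frame)
    abort_argument(sprintf(
      "noise template length (%d) must equal the FFT frame length (%d)",
      length(template), frame))
  if (hop * 2L != frame)
    abort_argument("spectral subtraction requires hop = frame / 2")
  y <- spectral_subtract_cpp(audio$samples, as.numeric(template),
                             alpha, floor_frac)
  audio_recording(as.numeric(y), audio$sample_rate, audio$start_time)
}

#' Short-term RMS envelope
#'
#' Divides the signal into short windows and computes the envelope value
#' `E = sqrt(mean(x_i^2))` per window -- the airflow-proxy curve used for
#' breath detection. A constant signal of amplitude `a` has envelope `|a|`.
#'
#' @param audio an [audio_recording()].
#' @param window_s window length in seconds (default 0.2).
#' @param hop_s hop between windows in seconds (default 0.05,
#'   must be `<= window_s`).
#' @param kind `"rms"` (default) or `"mean_abs"` (mean absolute amplitude
#'   per window, an alternative airflow proxy).
#' @return an `envelope_series`: `values` (one per window), window/hop in
#'   seconds, and `times` (window centers, seconds).
#' @export
envelope <- function(audio, window_s = 0.2, hop_s = 0.05,
                     kind = c("rms", "mean_abs")) {
  stopifnot(inherits(audio, "audio_recording"))
  kind <- match.arg(kind)
  if (window_s <= 0 || hop_s <= 0 || hop_s > window_s)
    abort_argument("need 0 < hop_s <= window_s")
  fs <- audio$sample_rate
  N <- max(1L, round(window_s * fs))
  hop <- max(1L, round(hop_s * fs))
  n <- length(audio$samples)
  if (N > n)
    abort_argument("envelope window longer than the signal")
  cs <- if (kind == "rms") c(0, cumsum(audio$samples^2))
        else c(0, cumsum(abs(audio$samples)))
  starts <- seq(1L, n - N + 1L, by = hop)
  values <- if (kind == "rms") sqrt(pmax(0, cs[starts + N] - cs[starts]) / N)
            else pmax(0, cs[starts + N] - cs[starts]) / N
  structure(list(values = values, window_seconds = N / fs,
                 hop_seconds = hop / fs,
                 times = audio$start_time + (starts - 1L) / fs + N / (2 * fs)),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d windows (%.0f ms window, %.0f ms hop)\n",
              length(x$values), 1000 * x$window_seconds, 1000 * x$hop_seconds))
  invisible(x)
}
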