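#' Heart beat series
#'
#' Detected heart beats (timed at the first peak of the S1/S2 pair), the
#' intervals between successive beats (NN intervals) and a per-beat flag
#' marking beats that were filled in by interpolation.
#'
#' @param beat_times beat times in seconds, strictly increasing.
#' @param interpolated logical per-beat flag.
#' @return an object of class `beat_series` with `beat_times`,
#'   `nn_intervals` (`diff(beat_times)`) and `interpolated_mask`.
#' @export
beat_series <- function(beat_times, interpolated = rep(FALSE, length(beat_times))) {
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0))
    abort_argument("beat times must be strictly increasing")
  if (length(interpolated) != length(beat_times))
    abort_argument("`interpolated` must match `beat_times` in length")
  structure(list(beat_times = as.numeric(beat_times),
                 nn_intervals = diff(as.numeric(beat_times)),
                 interpolated_mask = as.logical(interpolated)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats (%d interpolated)",
              length(x$beat_times), sum(x$interpolated_mask)))
  if (length(x$nn_intervals))
    cat(sprintf(", median NN %.3f s", stats::median(x$nn_intervals)))
  cat("\n")
  invisible(x)
}

#' Band-pass filter for the heart-sound band
#'
#' Suppresses breathing sound and most artefacts by restricting the signal
#' to the 5--30 Hz band where the S1/S2 heart sounds live. High-rate audio
#' is first anti-alias filtered and decimated to `target_fs` (default
#' 250 Hz) so the narrow band-pass stays cheap and well conditioned; the
#' result is effectively zero phase (symmetric FIR, delay compensated).
#'
#' @param audio an [audio_recording()] with sample rate >= 60 Hz.
#' @param band passband edges in Hz (default `c(5, 30)`).
#' @param target_fs decimation target in Hz.
#' @return a filtered [audio_recording()] at the decimated rate.
#' @export
bandpass_cardiac <- function(audio, band = c(5, 30), target_fs = 250) {
  stopifnot(inherits(audio, "audio_recording"))
  if (audio$sample_rate < 60)
    abort_argument("cardiac band-pass needs a sample rate of at least 60 Hz")
  x <- audio$samples
  fs <- audio$sample_rate
  if (fs > target_fs * 1.5) {
    q <- floor(fs / target_fs)
    lp <- design_fir(fs, high = 0.8 * (fs / q) / 2)
    x <- apply_fir(x, lp)[seq(1L, length(x), by = q)]
    fs <- fs / q
  }
  b <- design_fir(fs, band[1], band[2], order = as.integer(round(fs * 1.2)))
  audio_recording(apply_fir(x, b), fs, audio$start_time)
}

#' Detect heart-sound peaks
#'
#' Smooths the magnitude of the band-passed signal into an envelope, then
#' takes local maxima above an adaptive threshold (`median + k * MAD`),
#' enforcing a refractory separation so one physical sound yields one peak.
#' The narrow 5--30 Hz band makes the envelope of pure background noise
#' broadly spread relative to its median, so the default `k = 5` places the
#' threshold above essentially all noise maxima while staying far below
#' genuine heart-sound peaks.
#'
#' @param filtered output of [bandpass_cardiac()].
#' @param k MAD multiplier of the adaptive threshold (default 5).
#' @param refractory_s minimum separation between peaks in seconds
#'   (default 0.08).
#' @param smooth_s envelope moving-average length in seconds (default 0.04).
#' @return numeric vector of peak times (seconds), sorted; empty for a
#'   silent signal.
#' @export
detect_peaks <- function(filtered, k = 5, refractory_s = 0.08, smooth_s = 0.04) {
  stopifnot(inherits(filtered, "audio_recording"))
  fs <- filtered$sample_rate
  m <- max(1L, round(smooth_s * fs))
  cs <- c(0, cumsum(abs(filtered$samples)))
  n <- length(filtered$samples)
  starts <- 1L:(n - m + 1L)
  env <- (cs[starts + m] - cs[starts]) / m          # moving-average |x|
  ## spread estimated from the lower half of the envelope distribution:
  ## heart sounds inflate only the upper tail, so the threshold tracks the
  ## noise floor regardless of how much of the record is beat energy
  med <- stats::median(env)
  low_dev <- med - env[env < med]
  lmad <- 1.4826 * stats::median(low_dev)
  if (!length(low_dev) || !is.finite(lmad)) lmad <- stats::mad(env)
  thr <- med + k * lmad
  if (!is.finite(thr) || thr <= 0) return(numeric(0))
  ne <- length(env)
  if (ne < 3L) return(numeric(0))
  is_peak <- env[2:(ne - 1L)] > env[1:(ne - 2L)] &
             env[2:(ne - 1L)] >= env[3:ne] &
             env[2:(ne - 1L)] > thr
  cand <- which(is_peak) + 1L
  if (!length(cand)) return(numeric(0))
  ## local-prominence gate: band-edge filter ringing produces sidelobe
  ## trains around loud sounds; a candidate must reach a fixed fraction of
  ## the strongest envelope value in its neighborhood (S2 is ~half of S1,
  ## so genuine second sounds pass comfortably)
  half_w <- round(0.35 * fs)
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - half_w); hi <- min(ne, i + half_w)
    env[i] >= 0.25 * max(env[lo:hi])
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand)) return(numeric(0))
  ## greedy refractory pruning: strongest peaks first
  ord <- cand[order(env[cand], decreasing = TRUE)]
  refr <- refractory_s * fs
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) >= refr)) taken <- c(taken, i)
  }
  taken <- sort(taken)
  filtered$start_time + (taken - 1L + (m - 1L) / 2) / fs
}

#' Pair S1/S2 peaks into heart beats
#'
#' Greedy minimal-distance grouping: among all peak pairs whose gap lies in
#' the S1--S2 plausibility window, repeatedly take the smallest gap whose
#' two peaks are still unused and emit one beat timed at the pair's first
#' peak (the S1, matching the ECG R-peak convention). Leftover unpaired
#' peaks are discarded. Beats closer than the minimum plausible NN interval
#' are deduplicated (the earlier beat wins); long gaps are left for
#' [interpolate_beats()].
#'
#' @param peaks sorted peak times from [detect_peaks()].
#' @param s1s2_window_s plausible S1-to-S2 gap in seconds
#'   (default `c(0.15, 0.45)`).
#' @param nn_bounds_s plausible NN interval range in seconds
#'   (default `c(0.33, 1.5)`, i.e. 40--180 bpm).
#' @return a [beat_series()]; empty when fewer than 2 peaks are supplied.
#' @export
pair_peaks_to_beats <- function(peaks, s1s2_window_s = c(0.15, 0.45),
                                nn_bounds_s = c(0.33, 1.5)) {
  peaks <- as.numeric(peaks)
  if (is.unsorted(peaks)) abort_argument("`peaks` must be sorted")
  n <- length(peaks)
  if (n < 2L) return(beat_series(numeric(0)))
  ## candidate pairs: peaks within the S1-S2 window of each other; since the
  ## window is short, only a few successors per peak qualify
  i <- integer(0); j <- integer(0)
  for (d in 1L:(n - 1L)) {
    a <- 1L:(n - d)
    gap <- peaks[a + d] - peaks[a]
    ok <- gap >= s1s2_window_s[1] & gap <= s1s2_window_s[2]
    if (!any(ok)) { if (all(gap > s1s2_window_s[2])) break else next }
    i <- c(i, a[ok]); j <- c(j, a[ok] + d)
  }
  if (!length(i)) return(beat_series(numeric(0)))
  gap <- peaks[j] - peaks[i]
  ord <- order(gap, peaks[i])
  used <- logical(n)
  first <- numeric(0)
  for (k in ord) {
    if (!used[i[k]] && !used[j[k]]) {
      used[i[k]] <- used[j[k]] <- TRUE
      first <- c(first, peaks[i[k]])
    }
  }
  first <- sort(first)
  ## enforce the minimum plausible NN: drop the later of any too-close pair
  if (length(first) > 1L) {
    keep <- c(TRUE, rep(NA, length(first) - 1L))
    last <- first[1]
    for (k in 2L:length(first)) {
      keep[k] <- (first[k] - last) >= nn_bounds_s[1]
      if (keep[k]) last <- first[k]
    }
    first <- first[keep]
  }
  beat_series(first)
}

#' Interpolate heart beats across detection gaps
#'
#' Microphone-coupling loss, movements and similar artefacts leave gaps in
#' the detected beat train. Gaps longer than `trigger` times the rolling
#' median of the preceding `horizon` NN intervals are filled with evenly
#' spaced synthetic beats at approximately that preceding median spacing;
#' inserted beats are flagged in `interpolated_mask`. A gap at the start of
#' the recording (no preceding intervals) is left unfilled.
#'
#' @param beats a [beat_series()] from [pair_peaks_to_beats()].
#' @param trigger gap factor that triggers interpolation (default 1.5).
#' @param horizon number of preceding NN intervals in the rolling median
#'   (default 10).
#' @return a [beat_series()] including interpolated beats; returned
#'   unchanged (with a warning) when fewer than 5 beats were detected.
#' @export
interpolate_beats <- function(beats, trigger = 1.5, horizon = 10L) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$beat_times) < 5L) {
    warning("fewer than 5 detected beats; skipping interpolation")
    return(beats)
  }
  t <- beats$beat_times
  nn <- diff(t)
  out_t <- t[1]
  out_f <- FALSE
  hist <- numeric(0)  # preceding *detected* NN intervals only
  for (k in seq_along(nn)) {
    gap <- nn[k]
    med <- if (length(hist)) stats::median(utils::tail(hist, horizon)) else NA_real_
    if (!is.na(med) && gap > trigger * med) {
      n_fill <- max(1L, round(gap / med) - 1L)
      fill <- t[k] + seq_len(n_fill) * gap / (n_fill + 1L)
      out_t <- c(out_t, fill)
      out_f <- c(out_f, rep(TRUE, n_fill))
    } else {
      hist <- c(hist, gap)
    }
    out_t <- c(out_t, t[k + 1L])
    out_f <- c(out_f, FALSE)
  }
  beat_series(out_t, out_f)
}

cardiac_feature_names <- c(
  "card_hr", "card_nn_mean", "card_sdnn", "card_rmssd", "card_pnn50",
  "card_nn_cv", "card_nn_ac1", "card_lf", "card_hf", "card_lf_hf",
  "card_lf_norm", "card_frac_interp", "card_nn_range")

## band power of the NN tachogram resampled at `fs` Hz, by periodogram
nn_band_powers <- function(times, nn, w_lo, w_hi, fs = 4) {
  if (length(nn) < 8L) return(c(lf = NA_real_, hf = NA_real_))
  grid <- seq(max(w_lo, times[1]), min(w_hi, times[length(times)]), by = 1 / fs)
  if (length(grid) < 64L) return(c(lf = NA_real_, hf = NA_real_))
  x <- stats::approx(times, nn, xout = grid, rule = 2)$y
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / (n * fs)      # one-sided density up to fs/2
  freqs <- (0:(n - 1L)) * fs / n
  df <- fs / n
  lf <- 2 * sum(p[freqs >= 0.04 & freqs < 0.15]) * df
  hf <- 2 * sum(p[freqs >= 0.15 & freqs < 0.40]) * df
  c(lf = lf, hf = hf)
}

#' Per-epoch cardiac (HRV) features
#'
#' Thirteen features per 30-s epoch, centred on heart-rate variability.
#' Time-domain statistics (mean HR, mean NN, SDNN, RMSSD, pNN50, CV, lag-1
#' autocorrelation, range) use beats within the epoch +/- `context_s`;
#' spectral power (LF 0.04--0.15 Hz, HF 0.15--0.4 Hz, their ratio and
#' normalized LF) uses the epoch +/- `spectral_context_s` because spectral
#' HRV needs several minutes of tachogram (resampled at 4 Hz). Features
#' that cannot be computed are `NA` with the `imputed` flag set.
#'
#' @param beats a [beat_series()] (after [interpolate_beats()]).
#' @param epoch 0-based epoch index.
#' @param grid an `epoch_grid`.
#' @param context_s half-width of the time-domain window (default 60).
#' @param spectral_context_s half-width of the spectral window (default 120).
#' @return a list with `values` (named numeric 13-vector) and `imputed`
#'   (logical 13-vector).
#' @export
cardiac_features <- function(beats, epoch, grid, context_s = 60,
                             spectral_context_s = 120) {
  b <- epoch_bounds(grid, epoch)
  t <- beats$beat_times
  w_lo <- b["start"] - context_s; w_hi <- b["end"] + context_s
  sel <- which(t >= w_lo & t < w_hi)
  nn <- if (length(sel) >= 2L) diff(t[sel]) else numeric(0)
  st <- interval_stats(nn)
  hr <- if (!is.na(st["mean"])) 60 / st["mean"] else NA_real_
  pnn50 <- if (length(nn) >= 2L) 100 * mean(abs(diff(nn)) > 0.05) else NA_real_

  s_lo <- b["start"] - spectral_context_s; s_hi <- b["end"] + spectral_context_s
  ssel <- which(t >= s_lo & t < s_hi)
  pw <- if (length(ssel) >= 2L) {
    ts <- t[ssel][-1]  # tachogram: NN value at the time of the closing beat
    nn_band_powers(ts, diff(t[ssel]), s_lo, s_hi)
  } else c(lf = NA_real_, hf = NA_real_)
  lf_hf <- if (all(is.finite(pw)) && pw["hf"] > 0) pw[["lf"]] / pw[["hf"]] else NA_real_
  lf_norm <- if (all(is.finite(pw)) && sum(pw) > 0) pw[["lf"]] / sum(pw) else NA_real_

  frac_interp <- if (length(sel)) mean(beats$interpolated_mask[sel]) else NA_real_

  values <- c(hr, st[["mean"]], st[["sd"]], st[["rmssd"]], pnn50, st[["cv"]],
              st[["ac1"]], pw[["lf"]], pw[["hf"]], lf_hf, lf_norm,
              frac_interp, st[["range"]])
  names(values) <- cardiac_feature_names
  list(values = values, imputed = is.na(values))
}
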