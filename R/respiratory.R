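#' Breath event series
#'
#' Detected breath onsets, the intervals between successive breaths
#' (BB intervals) and the peak envelope amplitude of each breath.
#'
#' @param onset_times breath onset times in seconds, strictly increasing.
#' @param amplitudes peak envelope value per breath.
#' @param threshold envelope threshold used by the detector (kept for the
#'   per-epoch "fraction above threshold" feature).
#' @return an object of class `breath_series` with `onset_times`,
#'   `bb_intervals` (`diff(onset_times)`) and `amplitudes`.
#' @export
breath_series <- function(onset_times, amplitudes = rep(NA_real_, length(onset_times)),
                          threshold = NA_real_) {
  if (length(onset_times) > 1L && any(diff(onset_times) <= 0))
    abort_argument("breath onsets must be strictly increasing")
  if (length(amplitudes) != length(onset_times))
    abort_argument("`amplitudes` must match `onset_times` in length")
  structure(list(onset_times = as.numeric(onset_times),
                 bb_intervals = diff(as.numeric(onset_times)),
                 amplitudes = as.numeric(amplitudes),
                 threshold = threshold),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d breaths", length(x$onset_times)))
  if (length(x$bb_intervals))
    cat(sprintf(", median BB %.2f s", stats::median(x$bb_intervals)))
  cat("\n")
  invisible(x)
}

#' Detect breath cycles on an envelope curve
#'
#' Thresholds the short-term envelope at `threshold_factor` times its
#' median (the "no breathing" line): maximal runs above the threshold whose
#' duration is physiologically plausible become breath events, with onset at
#' the run start and amplitude at the run maximum.
#'
#' @param env an `envelope_series` (see [envelope()]) spanning at least 10 s.
#' @param threshold_factor multiple of the median envelope (default 1.2).
#' @param min_duration_s,max_duration_s plausible breath-sound duration
#'   bounds in seconds (defaults 0.3 and 10).
#' @return a [breath_series()].
#' @export
detect_breaths <- function(env, threshold_factor = 1.2,
                           min_duration_s = 0.3, max_duration_s = 10) {
  stopifnot(inherits(env, "envelope_series"))
  if (!length(env$values))
    abort_argument("empty envelope")
  span <- length(env$values) * env$hop_seconds + env$window_seconds
  if (span < 10)
    abort_argument("breath detection needs an envelope spanning at least 10 s")
  thr <- threshold_factor * stats::median(env$values)
  above <- env$values > thr
  if (!any(above)) return(breath_series(numeric(0), numeric(0), threshold = thr))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  dur <- r$lengths[keep] * env$hop_seconds
  ok <- dur >= min_duration_s & dur <= max_duration_s
  s <- starts[keep][ok]; e <- ends[keep][ok]
  onsets <- env$times[s] - env$window_seconds / 2  # run start, leading window edge
  amps <- vapply(seq_along(s), function(i) max(env$values[s[i]:e[i]]), numeric(1))
  breath_series(onsets, amps, threshold = thr)
}

## interval-series statistics shared by the respiratory and cardiac blocks;
## returns NA where undefined (caller flags/imputes)
interval_stats <- function(iv) {
  n <- length(iv)
  if (n < 1L) return(c(mean = NA_real_, sd = NA_real_, cv = NA_real_,
                       rmssd = NA_real_, range = NA_real_, ac1 = NA_real_))
  m <- mean(iv)
  s <- if (n >= 2L) stats::sd(iv) else NA_real_
  cv <- if (!is.na(s)) s / m else NA_real_
  rmssd <- if (n >= 2L) sqrt(mean(diff(iv)^2)) else NA_real_
  rg <- max(iv) - min(iv)
  ac1 <- NA_real_
  if (n >= 3L) {
    ac1 <- if (isTRUE(s > 0)) {
      x0 <- iv - m
      sum(x0[-n] * x0[-1]) / sum(x0^2)
    } else 0  # constant series: autocorrelation undefined, report 0
  }
  c(mean = m, sd = s, cv = cv, rmssd = rmssd, range = rg, ac1 = ac1)
}

## peak frequency of a series' periodogram restricted to [f_lo, f_hi] Hz
band_peak_frequency <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  if (n < 8L) return(NA_real_)
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  p <- Mod(stats::fft(x))^2
  freqs <- (0:(n - 1L)) * fs / n
  sel <- which(freqs >= f_lo & freqs <= f_hi & freqs <= fs / 2)
  if (!length(sel)) return(NA_real_)
  freqs[sel[which.max(p[sel])]]
}

respiratory_feature_names <- c(
  "resp_rate", "resp_bb_mean", "resp_bb_sd", "resp_bb_cv", "resp_bb_rmssd",
  "resp_bb_range", "resp_bb_ac1", "resp_amp_mean", "resp_amp_sd",
  "resp_amp_cv", "resp_env_energy", "resp_frac_active", "resp_env_peak_hz")

#' Per-epoch respiratory features
#'
#' Thirteen features per 30-s epoch. BB-interval statistics (rate, mean, SD,
#' CV, RMSSD, range, lag-1 autocorrelation) are computed over a centered
#' context window of the epoch +/- `context_s`, because a single epoch holds
#' too few breaths for stable variability estimates; amplitude and envelope
#' features use the epoch alone. BB intervals outside `bb_bounds_s` are
#' treated as implausible and dropped before statistics. Features that
#' cannot be computed (no events) are returned as `NA` with their
#' `imputed` flag set; [assemble_features()] fills them with the recording
#' median.
#'
#' @param breaths a [breath_series()].
#' @param env the `envelope_series` the breaths were detected on.
#' @param epoch 0-based epoch index.
#' @param grid an `epoch_grid`.
#' @param context_s half-width of the interval-statistics window (default 60).
#' @param bb_bounds_s plausible BB interval range in seconds
#'   (default `c(1, 15)`, i.e. 4--60 breaths/min).
#' @return a list with `values` (named numeric 13-vector) and `imputed`
#'   (logical 13-vector).
#' @export
respiratory_features <- function(breaths, env, epoch, grid, context_s = 60,
                                 bb_bounds_s = c(1, 15)) {
  b <- epoch_bounds(grid, epoch)
  w_lo <- b["start"] - context_s; w_hi <- b["end"] + context_s

  on <- breaths$onset_times
  in_ctx <- on >= w_lo & on < w_hi
  bb <- diff(on[in_ctx])
  bb <- bb[bb >= bb_bounds_s[1] & bb <= bb_bounds_s[2]]
  st <- interval_stats(bb)
  rate <- if (!is.na(st["mean"])) 60 / st["mean"] else NA_real_

  in_ep <- on >= b["start"] & on < b["end"]
  amps <- breaths$amplitudes[in_ep]
  amp_mean <- if (length(amps)) mean(amps) else NA_real_
  amp_sd <- if (length(amps) >= 2L) stats::sd(amps) else NA_real_
  amp_cv <- if (!is.na(amp_sd) && isTRUE(amp_mean > 0)) amp_sd / amp_mean else
    if (length(amps) >= 2L) 0 else NA_real_

  ep_env <- env$values[env$times >= b["start"] & env$times < b["end"]]
  energy <- if (length(ep_env)) mean(ep_env^2) else NA_real_
  frac <- if (length(ep_env) && is.finite(breaths$threshold))
    mean(ep_env > breaths$threshold) else NA_real_

  ctx_env <- env$values[env$times >= w_lo & env$times < w_hi]
  peak_hz <- band_peak_frequency(ctx_env, 1 / env$hop_seconds, 0.1, 0.5)

  values <- c(rate, st[["mean"]], st[["sd"]], st[["cv"]], st[["rmssd"]],
              st[["range"]], st[["ac1"]], amp_mean, amp_sd, amp_cv,
              energy, frac, peak_hz)
  names(values) <- respiratory_feature_names
  list(values = values, imputed = is.na(values))
}
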