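## Synthetic stage-annotated nights: a first-order Markov hypnogram over
## 30-s epochs drives per-stage cardiorespiratory and movement physiology,
## from which tracheal audio (breath-band noise bursts + paired 20 Hz heart
## pulses + white background noise) and a 6-axis IMU stream (gravity per
## position, transition rotations, movement bursts) are synthesized along
## with ground-truth event times.

#' Simulation configuration
#'
#' Per-stage physiology defaults encode the directions the classifier
#' relies on: slow, regular respiration and low HRV in deep sleep; fast,
#' irregular respiration and the highest HRV in REM; movement concentrated
#' in wake. `wake_bias` in `[0, 1]` interpolates the stage-transition
#' matrix between a consolidated sleeper (0) and a highly fragmented,
#' wake-dominated night (1), which is how a cohort acquires a wide
#' sleep-efficiency spread.
#'
#' @param night_minutes recording length in minutes (default 120).
#' @param snr_db broadband audio SNR in dB: breath-burst power over white
#'   background-noise power (default 10); `Inf` disables noise.
#' @param wake_bias default sleep-fragmentation level (default 0.25).
#' @param audio_fs,imu_fs sample rates in Hz (defaults 5000 and 250).
#' @param stage_params data frame (rows W, REM, N1, N2, N3) with columns
#'   `br` (breaths/min), `bb_cv`, `hr` (bpm), `sdnn_ms`, `lfhf`,
#'   `move_rate_h` (bursts/hour), `pos_change_prob` (per epoch).
#' @return a `sim_config` list.
#' @export
sim_config <- function(night_minutes = 120, snr_db = 10, wake_bias = 0.25,
                       audio_fs = 5000, imu_fs = 250,
                       stage_params = default_stage_params()) {
  if (night_minutes <= 0) abort_argument("`night_minutes` must be positive")
  if (!all(rownames(stage_params) == stage_alphabets$raw))
    abort_argument("stage_params rows must be W, REM, N1, N2, N3")
  if (any(stage_params$br <= 0) || any(stage_params$hr <= 0))
    abort_argument("stage rates must be positive")
  structure(list(night_minutes = night_minutes, snr_db = snr_db,
                 wake_bias = wake_bias, audio_fs = audio_fs, imu_fs = imu_fs,
                 stage_params = stage_params),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_stage_params <- function() {
  data.frame(
    row.names = c("W", "REM", "N1", "N2", "N3"),
    br   = c(16,  18,   15,   14,   12),    # breaths/min
    bb_cv = c(0.25, 0.30, 0.15, 0.10, 0.05),
    hr   = c(70,  68,   65,   60,   55),    # bpm
    sdnn_ms = c(50, 70,  45,   35,   20),
    lfhf = c(3.0, 2.5,  2.0,  1.0,  0.5),
    move_rate_h = c(60, 2,  6,    2,   0.5),
    pos_change_prob = c(0.10, 0.01, 0.03, 0.01, 0.005))
}

## Epoch-to-epoch stage transition matrices (rows sum to 1; order
## W, REM, N1, N2, N3). "consolidated" emulates an efficient sleeper,
## "fragmented" a wake-dominated, arousal-rich night.
transition_matrix <- function(wake_bias = 0.25) {
  if (wake_bias < 0 || wake_bias > 1)
    abort_argument("`wake_bias` must be in [0, 1]")
  consolidated <- matrix(c(
    0.70, 0.01, 0.24, 0.05, 0.00,
    0.04, 0.88, 0.05, 0.03, 0.00,
    0.06, 0.05, 0.64, 0.25, 0.00,
    0.02, 0.04, 0.06, 0.79, 0.09,
    0.01, 0.00, 0.01, 0.14, 0.84), 5, 5, byrow = TRUE)
  fragmented <- matrix(c(
    0.97, 0.005, 0.020, 0.005, 0.00,
    0.25, 0.650, 0.070, 0.030, 0.00,
    0.35, 0.030, 0.440, 0.180, 0.00,
    0.15, 0.030, 0.070, 0.700, 0.05,
    0.08, 0.000, 0.020, 0.180, 0.72), 5, 5, byrow = TRUE)
  P <- (1 - wake_bias) * consolidated + wake_bias * fragmented
  dimnames(P) <- list(stage_alphabets$raw, stage_alphabets$raw)
  P
}

#' Simulate a raw hypnogram
#'
#' First-order Markov chain over 30-s epochs, starting in W.
#'
#' @param cfg a [sim_config()] (supplies `night_minutes`).
#' @param transition 5x5 row-stochastic matrix over W, REM, N1, N2, N3;
#'   defaults to [transition_matrix()] at `cfg$wake_bias`.
#' @return a raw [hypnogram()].
#' @export
simulate_hypnogram <- function(cfg = sim_config(),
                               transition = transition_matrix(cfg$wake_bias)) {
  if (!is.matrix(transition) || any(dim(transition) != 5L) ||
      any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    abort_argument("`transition` must be a 5x5 row-stochastic matrix")
  n <- as.integer(floor(cfg$night_minutes * 2))
  labels <- character(n)
  state <- 1L  # W
  for (k in seq_len(n)) {
    labels[k] <- stage_alphabets$raw[state]
    state <- sample.int(5L, 1L, prob = transition[state, ])
  }
  hypnogram(labels, "raw")
}

## stage label at an arbitrary time, from a raw hypnogram
stage_at <- function(hyp, t) {
  k <- pmin(length(hyp$labels), pmax(1L, floor(t / 30) + 1L))
  hyp$labels[k]
}

#' Simulate tracheal audio for a hypnogram
#'
#' Breaths are 200--2000 Hz band-limited noise bursts (~1.4 s, Hann-shaped)
#' whose onset intervals follow the stage's BB mean and CV; heart beats are
#' pairs of 20 Hz Gabor pulses 0.3 s apart whose NN intervals follow the
#' stage's HR and SDNN with an LF/HF-shaped oscillatory modulation. White
#' background noise is added at `cfg$snr_db` (breath-burst power over noise
#' power). Beats ride on top of breath sound, so the band-separated
#' extractors face realistic crosstalk.
#'
#' @param hyp a raw [hypnogram()].
#' @param cfg a [sim_config()].
#' @return a list with `audio` (an [audio_recording()]), `breath_onsets`,
#'   `beat_times` (first-peak/S1 times) and `nn_true` (seconds).
#' @export
simulate_audio <- function(hyp, cfg = sim_config()) {
  fs <- cfg$audio_fs
  dur <- length(hyp$labels) * 30
  n <- as.integer(dur * fs)
  sp <- cfg$stage_params

  ## breath onset process: gamma-distributed BB intervals hit the stage's
  ## mean/CV exactly (no truncation bias), as interval processes should
  onsets <- numeric(0); durs <- numeric(0)
  t <- stats::runif(1, 0, 2)
  while (t < dur - 2) {
    st <- stage_at(hyp, t)
    bb_mean <- 60 / sp[st, "br"]
    cv <- sp[st, "bb_cv"]
    bb <- if (cv > 0)
      stats::rgamma(1, shape = 1 / cv^2, scale = bb_mean * cv^2)
    else bb_mean
    bb <- max(1.2, bb)
    onsets <- c(onsets, t)
    durs <- c(durs, min(1.4, 0.55 * bb))
    t <- t + bb
  }

  ## heart beat process: NN = base * (1 + LF + HF sinusoids + jitter)
  phi_lf <- stats::runif(1, 0, 2 * pi); phi_hf <- stats::runif(1, 0, 2 * pi)
  f_lf <- 0.095; f_hf <- 0.24
  beats <- numeric(0)
  t <- stats::runif(1, 0, 1)
  while (t < dur - 1) {
    st <- stage_at(hyp, t)
    base <- 60 / sp[st, "hr"]
    sdnn <- sp[st, "sdnn_ms"] / 1000
    ratio <- sp[st, "lfhf"]
    ## split variance: LF/HF sinusoids (90%) + white jitter (10%)
    s_osc <- sdnn * sqrt(0.9); s_j <- sdnn * sqrt(0.1)
    a_hf <- s_osc * sqrt(2 / (1 + ratio))
    a_lf <- a_hf * sqrt(ratio)
    mod <- a_lf * sin(2 * pi * f_lf * t + phi_lf) +
           a_hf * sin(2 * pi * f_hf * t + phi_hf) +
           stats::rnorm(1, 0, s_j)
    nn <- max(0.4, base + mod)
    beats <- c(beats, t)
    t <- t + nn
  }

  ## assemble: breath gate * white noise, band-limited in one FIR pass
  x <- numeric(n)
  for (i in seq_along(onsets)) {
    i0 <- as.integer(onsets[i] * fs) + 1L
    len <- max(2L, as.integer(durs[i] * fs))
    i1 <- min(n, i0 + len - 1L)
    seg <- i0:i1
    x[seg] <- x[seg] + hann_periodic(len)[seq_along(seg)] * stats::rnorm(length(seg))
  }
  b <- design_fir(fs, 200, 2000, order = 256L)
  x <- apply_fir(x, b)
  breath_rms <- sqrt(mean(x[x != 0]^2))
  if (!is.finite(breath_rms) || breath_rms == 0) breath_rms <- 1

  ## heart pulses: 20 Hz Gabor at S1 and S2 (+0.3 s)
  half <- as.integer(0.08 * fs)
  tt <- (-half:half) / fs
  gabor <- cos(2 * pi * 20 * tt) * exp(-tt^2 / (2 * 0.025^2))
  amp1 <- 0.35 * breath_rms; amp2 <- 0.6 * amp1
  for (bt in beats) {
    for (off in c(0, 0.3)) {
      c0 <- as.integer((bt + off) * fs) + 1L
      seg <- max(1L, c0 - half):min(n, c0 + half)
      x[seg] <- x[seg] + (if (off == 0) amp1 else amp2) *
        gabor[seg - (c0 - half) + 1L]
    }
  }

  if (is.finite(cfg$snr_db)) {
    sigma <- breath_rms / 10^(cfg$snr_db / 20)
    x <- x + stats::rnorm(n, 0, sigma)
  }
  sc <- max(abs(x))
  if (sc > 0) x <- 0.98 * x / sc

  list(audio = audio_recording(x, fs),
       breath_onsets = onsets, beat_times = beats,
       nn_true = diff(beats))
}

#' Simulate an IMU stream for a hypnogram
#'
#' Gravity-consistent accelerometer traces for the current sleeping
#' position, smooth 3-s rotations at position changes (with matching
#' gyroscope rates), stage-dependent Poisson movement bursts (concentrated
#' in wake) and a small sensor noise floor.
#'
#' @param hyp a raw [hypnogram()].
#' @param cfg a [sim_config()].
#' @return a list with `imu` (an [imu_recording()]), `position_timeline`
#'   (factor per epoch) and `n_position_changes`.
#' @export
simulate_imu <- function(hyp, cfg = sim_config()) {
  fs <- cfg$imu_fs
  n_ep <- length(hyp$labels)
  n <- as.integer(n_ep * 30 * fs)
  sp <- cfg$stage_params
  g <- 9.80665
  mount <- default_mounting()
  lying <- c("supine", "left", "right", "prone")

  ## per-epoch position timeline
  pos <- character(n_ep)
  cur <- "supine"
  changes <- 0L
  for (k in seq_len(n_ep)) {
    p_chg <- sp[hyp$labels[k], "pos_change_prob"]
    if (stats::runif(1) < p_chg) {
      cur <- sample(setdiff(lying, cur), 1L)
      changes <- changes + 1L
    }
    pos[k] <- cur
  }

  accel <- matrix(0, n, 3)
  gyro <- matrix(0, n, 3)
  ## accel = -g * gravity_direction (reaction reading); fill per epoch run
  r <- rle(pos)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    i0 <- as.integer((starts[j] - 1L) * 30 * fs) + 1L
    i1 <- as.integer(ends[j] * 30 * fs)
    gdir <- mount[[r$values[j]]]
    accel[i0:i1, ] <- matrix(-g * gdir, i1 - i0 + 1L, 3, byrow = TRUE)
  }
  ## smooth the transitions: 3-s great-circle rotation + gyro rate
  if (length(r$values) > 1L) {
    half_tr <- as.integer(1.5 * fs)
    for (j in 2:length(r$values)) {
      c0 <- as.integer((starts[j] - 1L) * 30 * fs)
      seg <- max(1L, c0 - half_tr):min(n, c0 + half_tr)
      g1 <- mount[[r$values[j - 1L]]]; g2 <- mount[[r$values[j]]]
      ang <- acos(max(-1, min(1, sum(g1 * g2))))
      axis <- c(g1[2] * g2[3] - g1[3] * g2[2],
                g1[3] * g2[1] - g1[1] * g2[3],
                g1[1] * g2[2] - g1[2] * g2[1])
      an <- sqrt(sum(axis^2))
      if (an < 1e-9) next
      axis <- axis / an
      u <- seq(0, 1, length.out = length(seg))
      ## slerp of the gravity direction
      gs <- outer(sin((1 - u) * ang) / sin(ang), g1) +
            outer(sin(u * ang) / sin(ang), g2)
      accel[seg, ] <- -g * gs
      gyro[seg, ] <- matrix(-axis * ang / (length(seg) / fs),
                            length(seg), 3, byrow = TRUE)
    }
  }
  ## movement bursts
  for (k in seq_len(n_ep)) {
    rate <- sp[hyp$labels[k], "move_rate_h"] / 120   # per epoch
    nb <- stats::rpois(1, rate)
    if (nb == 0) next
    for (b in seq_len(nb)) {
      t0 <- (k - 1L) * 30 + stats::runif(1, 0, 28)
      len <- as.integer(stats::runif(1, 0.5, 2) * fs)
      i0 <- as.integer(t0 * fs) + 1L
      seg <- i0:min(n, i0 + len - 1L)
      env <- hann_periodic(length(seg))
      accel[seg, ] <- accel[seg, ] + env * matrix(stats::rnorm(3 * length(seg), 0, 2.0),
                                                  length(seg), 3)
      gyro[seg, ] <- gyro[seg, ] + env * matrix(stats::rnorm(3 * length(seg), 0, 0.5),
                                                length(seg), 3)
    }
  }
  ## sensor noise floor
  accel <- accel + matrix(stats::rnorm(3 * n, 0, 0.03), n, 3)
  gyro <- gyro + matrix(stats::rnorm(3 * n, 0, 0.005), n, 3)

  list(imu = imu_recording((0:(n - 1L)) / fs, accel, gyro, sample_rate = fs),
       position_timeline = factor(pos, levels = position_levels),
       n_position_changes = changes)
}

#' Simulate one full synthetic night
#'
#' Draws a hypnogram, audio and IMU stream under one derived RNG seed, so
#' a cohort is reproducible subject by subject.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for this night.
#' @param subject_id identifier attached to the outputs.
#' @return a `synthetic_night` list: `truth_hypnogram`, `audio`, `imu`,
#'   `truth` (breath onsets, beat times, NN intervals, position timeline)
#'   and `subject_id`.
#' @export
simulate_night <- function(cfg = sim_config(), seed = 1L,
                           subject_id = "subject1") {
  set.seed(as.integer(seed %% .Machine$integer.max))
  hyp <- simulate_hypnogram(cfg)
  au <- simulate_audio(hyp, cfg)
  im <- simulate_imu(hyp, cfg)
  structure(list(truth_hypnogram = hyp, audio = au$audio, imu = im$imu,
                 truth = list(breath_onsets = au$breath_onsets,
                              beat_times = au$beat_times,
                              nn_true = au$nn_true,
                              position_timeline = im$position_timeline,
                              n_position_changes = im$n_position_changes),
                 subject_id = subject_id),
            class = "synthetic_night")
}

#' @export
print.synthetic_night <- function(x, ...) {
  cat(sprintf("<synthetic_night> %s: %d epochs, %d breaths, %d beats\n",
              x$subject_id, length(x$truth_hypnogram$labels),
              length(x$truth$breath_onsets), length(x$truth$beat_times)))
  invisible(x)
}

## deterministic per-subject seed derived from a cohort seed (kept < 2^31)
subject_seed <- function(seed, i) (as.integer(seed) + 7919L * as.integer(i)) %% 2147480017L

#' Cohort wake-bias schedule
#'
#' Evenly spaced sleep-fragmentation levels across subjects, emulating a
#' referral cohort whose sleep efficiencies span from severely disrupted
#' to consolidated sleep.
#'
#' @param n_subjects cohort size.
#' @return numeric vector in `[0.05, 0.95]`.
#' @export
cohort_wake_bias <- function(n_subjects) {
  if (n_subjects == 1L) return(0.5)
  seq(0.95, 0.05, length.out = n_subjects)
}
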