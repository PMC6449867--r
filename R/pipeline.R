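#' Run the full feature-extraction chain on one recording
#'
#' Audio is resampled to the 5 kHz reference rate, then processed along the
#' two band-separated paths: breathing (band-pass 200--2000 Hz, spectral
#' subtraction of an estimated noise template, short-term envelope, breath
#' detection) and cardiac (band-pass 5--30 Hz after decimation, peak
#' detection, S1/S2 pairing, gap interpolation). The IMU is fused into an
#' orientation series and a position timeline. All three sources are
#' assembled into the 30-feature epoch matrix on the shared 30-s grid
#' (truncated to the shorter of the two recordings).
#'
#' @param audio an [audio_recording()].
#' @param imu an [imu_recording()].
#' @param config a [somnostage_config()].
#' @param subject_id identifier stored in the feature matrix.
#' @return a list with `features` (an [epoch_feature_matrix()]), `breaths`,
#'   `beats`, `positions` and `grid`.
#' @export
extract_features <- function(audio, imu, config = somnostage_config(),
                             subject_id = NA_character_) {
  audio <- resample_audio(audio, config$audio$reference_fs)
  grid <- align_to_epochs(min(duration(audio), duration(imu)))
  if (grid$n_epochs < 1L)
    abort_data("recording shorter than one 30-s epoch")

  ## respiratory path
  filtered <- bandpass_breath(audio, band = config$resp$band_hz)
  template <- estimate_noise_template(filtered, frame = config$resp$subtract_frame,
                                      quietest_frac = config$resp$noise_quantile)
  clean <- spectral_subtract(filtered, template,
                             frame = config$resp$subtract_frame,
                             alpha = config$resp$subtract_alpha,
                             floor_frac = config$resp$subtract_floor)
  env <- envelope(clean, config$resp$window_s, config$resp$hop_s,
                  kind = config$resp$envelope_kind)
  breaths <- detect_breaths(env, config$resp$threshold_factor,
                            config$resp$min_breath_s, config$resp$max_breath_s)

  ## cardiac path (from the raw audio, not the denoised breathing band)
  heart <- bandpass_cardiac(audio, band = config$cardiac$band_hz,
                            target_fs = config$cardiac$target_fs)
  peaks <- detect_peaks(heart, k = config$cardiac$mad_k,
                        refractory_s = config$cardiac$refractory_s,
                        smooth_s = config$cardiac$smooth_s)
  beats <- pair_peaks_to_beats(peaks, config$cardiac$s1s2_window_s,
                               config$cardiac$nn_bounds_s)
  beats <- tryCatch(
    interpolate_beats(beats, config$cardiac$interp_trigger,
                      config$cardiac$interp_horizon),
    warning = function(w) beats)

  ## movement path
  orientation <- madgwick_fuse(imu, beta = config$imu$beta)
  positions <- position_timeline(orientation, config$imu$mounting,
                                 config$imu$hysteresis_samples)

  features <- assemble_features(breaths, env, beats, imu, positions, grid,
                                config, subject_id = subject_id)
  list(features = features, breaths = breaths, beats = beats,
       positions = positions, grid = grid)
}

#' Simulate a cohort and extract its features
#'
#' Generates `n_subjects` synthetic nights (wake bias spread per
#' [cohort_wake_bias()], per-subject seeds derived from `seed`) and runs
#' [extract_features()] on each, discarding the raw signals immediately so
#' arbitrarily large cohorts fit in memory.
#'
#' @param n_subjects cohort size.
#' @param cfg a [sim_config()].
#' @param seed cohort seed.
#' @param config a [somnostage_config()].
#' @param keep_truth keep per-subject ground-truth event times
#'   (default TRUE).
#' @return list of subjects, each with `features`, `hypnogram` (truth raw
#'   hypnogram), `truth` (if kept) and `subject_id` -- the cohort shape
#'   consumed by [loocv()].
#' @export
build_cohort <- function(n_subjects, cfg = sim_config(), seed = 1L,
                         config = somnostage_config(), keep_truth = TRUE) {
  wb <- cohort_wake_bias(n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    cfg_i <- cfg
    cfg_i$wake_bias <- wb[i]
    night <- simulate_night(cfg_i, seed = subject_seed(seed, i),
                            subject_id = sprintf("subject%02d", i))
    ex <- extract_features(night$audio, night$imu, config,
                           subject_id = night$subject_id)
    out <- list(features = ex$features, hypnogram = night$truth_hypnogram,
                subject_id = night$subject_id)
    if (keep_truth) out$truth <- night$truth
    out
  })
}

#' Stage-conditional parameter recovery
#'
#' Compares the physiology the extraction chain reads out of a synthetic
#' cohort against the generator's configured per-stage parameters: mean
#' heart rate (bpm) and breathing rate (breaths/min) per sleep stage.
#' Because the per-epoch features deliberately use a context window wider
#' than one epoch, epochs at stage-run boundaries mix neighboring stages;
#' recovery is therefore measured on run-interior epochs only (an epoch
#' whose `half_width` neighbors on both sides share its stage).
#'
#' @param cohort output of [build_cohort()] (needs `features` and the truth
#'   `hypnogram` per subject).
#' @param stage_params the generator's per-stage table
#'   (default [default_stage_params()]).
#' @param half_width neighborhood half-width in epochs (default 2, matching
#'   the +/- 60 s feature context).
#' @return a data frame per stage: configured and estimated heart rate and
#'   breathing rate, their errors, and the number of epochs used.
#' @export
recover_stage_parameters <- function(cohort, stage_params = default_stage_params(),
                                     half_width = 2L) {
  stages <- rownames(stage_params)
  rows <- lapply(stages, function(st) {
    hr <- c(); br <- c()
    for (s in cohort) {
      labs <- s$hypnogram$labels
      n <- min(length(labs), nrow(s$features$values))
      interior <- vapply(seq_len(n), function(k) {
        lo <- max(1L, k - half_width); hi <- min(n, k + half_width)
        all(labs[lo:hi] == st)
      }, logical(1))
      hr <- c(hr, s$features$values[interior, "card_hr"])
      br <- c(br, s$features$values[interior, "resp_rate"])
    }
    data.frame(stage = st, n_epochs = length(hr),
               hr_config = stage_params[st, "hr"], hr_est = mean(hr),
               hr_error = mean(hr) - stage_params[st, "hr"],
               br_config = stage_params[st, "br"], br_est = mean(br),
               br_error = mean(br) - stage_params[st, "br"])
  })
  do.call(rbind, rows)
}

#' Run the staging pipeline on recording files
#'
#' File-level composition used by the command-line tool: reads audio, IMU
#' and a trained model, extracts features, predicts the hypnogram in the
#' model's stage system, and writes the predicted hypnogram CSV plus a
#' sleep-summary JSON (SE/TST/TWT/WASO, from the 2-stage view of the
#' prediction). Outputs are removed again if any stage of the run fails.
#'
#' @param audio_path WAV file.
#' @param imu_path IMU CSV file.
#' @param model_path model JSON from [write_ld_model()].
#' @param out_hypnogram,out_summary output paths.
#' @param config a [somnostage_config()].
#' @return invisibly, a list with the predicted `hypnogram` and `summary`.
#' @export
run_pipeline <- function(audio_path, imu_path, model_path,
                         out_hypnogram = "hypnogram.csv",
                         out_summary = "summary.json",
                         config = somnostage_config()) {
  cleanup <- function() unlink(c(out_hypnogram, out_summary))
  tryCatch({
    audio <- read_audio(audio_path)
    imu <- read_imu(imu_path)
    model <- read_ld_model(model_path)
    ex <- extract_features(audio, imu, config)
    pred <- predict_stages(model, ex$features)
    h2 <- if (model$system_id == "s2") pred$hypnogram else {
      ## any system collapses onto wake vs sleep for the summary
      hypnogram(ifelse(pred$hypnogram$labels == "W", "W", "S"), "s2")
    }
    summ <- sleep_summary(h2)
    write_hypnogram(pred$hypnogram, out_hypnogram)
    jsonlite::write_json(
      list(SE = summ$SE, TST = summ$TST, TWT = summ$TWT, WASO = summ$WASO,
           time_in_bed = summ$time_in_bed, n_epochs = length(pred$hypnogram$labels),
           system = model$system_id),
      out_summary, auto_unbox = TRUE, digits = NA)
    invisible(list(hypnogram = pred$hypnogram, summary = summ))
  }, error = function(e) { cleanup(); stop(e) })
}
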