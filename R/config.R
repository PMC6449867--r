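#' Pipeline configuration
#'
#' All tunables of the extraction and staging chain with their defaults.
#' Values supplied in `...` (as nested lists, e.g.
#' `resp = list(threshold_factor = 1.5)`) override the defaults; every
#' field is range-checked before any computation.
#'
#' @param ... nested overrides by module.
#' @return a validated `somnostage_config` list with sections `audio`,
#'   `resp`, `cardiac`, `imu` and `staging`.
#' @export
somnostage_config <- function(...) {
  cfg <- list(
    audio = list(reference_fs = 5000),
    resp = list(
      band_hz = c(200, 2000),
      window_s = 0.2, hop_s = 0.05,
      threshold_factor = 1.2,
      min_breath_s = 0.3, max_breath_s = 10,
      bb_bounds_s = c(1, 15),
      context_s = 60,
      subtract_frame = 1024L, subtract_alpha = 2, subtract_floor = 0.01,
      noise_quantile = 0.1,
      envelope_kind = "rms"),
    cardiac = list(
      band_hz = c(5, 30), target_fs = 250,
      smooth_s = 0.04, mad_k = 5, refractory_s = 0.08,
      s1s2_window_s = c(0.15, 0.45), nn_bounds_s = c(0.33, 1.5),
      interp_trigger = 1.5, interp_horizon = 10L,
      context_s = 60, spectral_context_s = 120),
    imu = list(beta = 0.1, hysteresis_samples = 5L,
               mounting = default_mounting()),
    staging = list(lambda = 0.1, priors = "empirical", median_filter = 0L))
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) abort_argument(sprintf("unknown config section: %s", sec))
    for (key in names(over[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        abort_argument(sprintf("unknown config key: %s.%s", sec, key))
      cfg[[sec]][[key]] <- over[[sec]][[key]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "somnostage_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort_argument(paste("config:", msg))
  chk(cfg$audio$reference_fs > 0, "audio.reference_fs must be positive")
  r <- cfg$resp
  chk(length(r$band_hz) == 2 && r$band_hz[1] > 0 && r$band_hz[1] < r$band_hz[2],
      "resp.band_hz must be increasing positive edges")
  chk(r$window_s > 0 && r$hop_s > 0 && r$hop_s <= r$window_s,
      "resp window/hop must satisfy 0 < hop <= window")
  chk(r$threshold_factor > 0, "resp.threshold_factor must be positive")
  chk(r$min_breath_s > 0 && r$min_breath_s < r$max_breath_s,
      "resp breath duration bounds must be increasing")
  chk(r$subtract_alpha >= 0 && r$subtract_floor >= 0 && r$subtract_floor < 1,
      "resp spectral subtraction parameters out of range")
  chk(r$noise_quantile > 0 && r$noise_quantile <= 1,
      "resp.noise_quantile must be in (0, 1]")
  chk(r$envelope_kind %in% c("rms", "mean_abs"),
      "resp.envelope_kind must be 'rms' or 'mean_abs'")
  cc <- cfg$cardiac
  chk(length(cc$band_hz) == 2 && cc$band_hz[1] > 0 && cc$band_hz[1] < cc$band_hz[2],
      "cardiac.band_hz must be increasing positive edges")
  chk(cc$target_fs >= 2 * cc$band_hz[2], "cardiac.target_fs below Nyquist of band")
  chk(cc$s1s2_window_s[1] > 0 && cc$s1s2_window_s[1] < cc$s1s2_window_s[2],
      "cardiac.s1s2_window_s must be increasing")
  chk(cc$nn_bounds_s[1] > 0 && cc$nn_bounds_s[1] < cc$nn_bounds_s[2],
      "cardiac.nn_bounds_s must be increasing")
  chk(cc$interp_trigger > 1, "cardiac.interp_trigger must exceed 1")
  chk(cfg$imu$beta >= 0, "imu.beta must be >= 0")
  chk(cfg$imu$hysteresis_samples >= 1, "imu.hysteresis_samples must be >= 1")
  chk(all(position_levels %in% names(cfg$imu$mounting)),
      "imu.mounting must name all five positions")
  chk(cfg$staging$lambda >= 0 && cfg$staging$lambda <= 1,
      "staging.lambda must be in [0, 1]")
  chk(cfg$staging$priors %in% c("empirical", "uniform"),
      "staging.priors must be 'empirical' or 'uniform'")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#' @param path file path.
#' @return `read_config()` returns a `somnostage_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$imu$mounting))
    raw$imu$mounting <- lapply(raw$imu$mounting, as.numeric)
  do.call(somnostage_config, raw)
}

#' @rdname read_config
#' @param config a `somnostage_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
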