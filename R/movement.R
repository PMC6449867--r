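position_levels <- c("supine", "prone", "left", "right", "upright")

## Mounting convention: unit direction of earth gravity (pointing down) in
## the sensor frame for each canonical body position. Default: sensor z
## dorsal-ventral (ventral = +z), y cranial-caudal (cranial = +y), x toward
## the subject's left.
default_mounting <- function() {
  list(supine  = c(0, 0, -1),
       prone   = c(0, 0,  1),
       left    = c(1, 0,  0),
       right   = c(-1, 0, 0),
       upright = c(0, -1, 0))
}

#' Fuse IMU data into an orientation series (Madgwick filter)
#'
#' Gradient-descent complementary filter: gyroscope quaternion integration
#' is corrected toward the accelerometer's gravity direction with gain
#' `beta` (rad/s). Samples with a zero-norm accelerometer reading get a
#' gyro-only update. The quaternion is renormalized every step.
#'
#' @param imu an [imu_recording()].
#' @param beta filter gain in rad/s (default 0.1, Madgwick's stable range).
#' @param q0 initial unit quaternion `(w, x, y, z)` (default identity).
#' @return an `orientation_series`: `quaternions` (n x 4 matrix, unit rows)
#'   and `sample_rate`.
#' @export
madgwick_fuse <- function(imu, beta = 0.1, q0 = c(1, 0, 0, 0)) {
  stopifnot(inherits(imu, "imu_recording"))
  if (beta < 0) abort_argument("`beta` must be >= 0")
  if (abs(sum(q0^2) - 1) > 1e-6) abort_argument("`q0` must be a unit quaternion")
  q <- madgwick_fuse_cpp(imu$accel, imu$gyro, 1 / imu$sample_rate, beta,
                         as.numeric(q0))
  colnames(q) <- c("w", "x", "y", "z")
  structure(list(quaternions = q, sample_rate = imu$sample_rate, t = imu$t),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples @ %.1f Hz\n",
              nrow(x$quaternions), x$sample_rate))
  invisible(x)
}

## gravity (down) direction in the sensor frame for quaternion rows (w,x,y,z)
gravity_in_sensor <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(-2 * (x * z - w * y), -2 * (w * x + y * z), -(1 - 2 * (x * x + y * y)))
}

#' Classify sleeping position from orientation
#'
#' Rotates earth gravity into the sensor frame and labels each sample by
#' the nearest mounting direction (supine, prone, left, right, upright).
#' Ties at sector boundaries are broken by that priority order, so a sample
#' exactly between supine and right is called supine. The labeling depends
#' only on the gravity direction, hence is invariant to rotation about the
#' gravity axis (yaw).
#'
#' @param orientation an `orientation_series` from [madgwick_fuse()], or a
#'   quaternion matrix / length-4 vector `(w, x, y, z)`.
#' @param mounting named list of unit gravity directions per position
#'   (default [default_mounting()] conventions).
#' @return factor of position labels, one per sample.
#' @export
classify_position <- function(orientation, mounting = default_mounting()) {
  q <- if (inherits(orientation, "orientation_series")) orientation$quaternions
       else if (is.matrix(orientation)) orientation
       else matrix(orientation, nrow = 1)
  if (ncol(q) != 4L) abort_argument("quaternions must have 4 components")
  g <- gravity_in_sensor(q)
  best <- rep(1L, nrow(g))
  best_score <- g %*% mounting[[position_levels[1]]]
  for (k in 2:length(position_levels)) {
    sc <- g %*% mounting[[position_levels[k]]]
    swap <- sc > best_score          # strict: earlier label wins ties
    best[swap] <- k
    best_score[swap] <- sc[swap]
  }
  factor(position_levels[best], levels = position_levels)
}

#' Position timeline with hysteresis
#'
#' Per-sample position labels with short-run suppression: a run of labels
#' shorter than `hysteresis_samples` is absorbed into the preceding
#' accepted position, so sensor jitter at sector boundaries does not
#' inflate the position-change count.
#'
#' @param orientation an `orientation_series`.
#' @param mounting see [classify_position()].
#' @param hysteresis_samples minimum run length to accept a new position
#'   (default 5).
#' @return a `position_series`: `labels` (factor per sample), `change_times`
#'   (seconds) and `sample_rate`.
#' @export
position_timeline <- function(orientation, mounting = default_mounting(),
                              hysteresis_samples = 5L) {
  labels <- classify_position(orientation, mounting)
  codes <- as.integer(labels)
  r <- rle(codes)
  if (length(r$lengths) > 1L) {
    for (k in 2:length(r$values)) {
      if (r$lengths[k] < hysteresis_samples) r$values[k] <- r$values[k - 1L]
    }
  }
  smoothed <- inverse.rle(r)
  t <- orientation$t %||% ((seq_along(smoothed) - 1L) / orientation$sample_rate)
  changes <- which(diff(smoothed) != 0L) + 1L
  structure(list(labels = factor(position_levels[smoothed], levels = position_levels),
                 change_times = t[changes], sample_rate = orientation$sample_rate,
                 t = t),
            class = "position_series")
}

#' @export
print.position_series <- function(x, ...) {
  cat(sprintf("<position_series> %d samples, %d position changes\n",
              length(x$labels), length(x$change_times)))
  invisible(x)
}

movement_feature_names <- c("move_position", "move_changes",
                            "move_accel", "move_gyro")

#' Per-epoch movement features
#'
#' Four features per 30-s epoch: the dominant sleeping position (mode of
#' per-sample labels, encoded 1 = supine ... 5 = upright), the number of
#' position changes, mean activity `| ||accel|| - g |` (gravity magnitude
#' subtracted so rest reads ~0 regardless of orientation) and mean
#' angular-velocity magnitude.
#'
#' @param imu an [imu_recording()].
#' @param positions a `position_series` from [position_timeline()].
#' @param epoch 0-based epoch index.
#' @param grid an `epoch_grid`.
#' @param gravity gravity magnitude in accel units; when `NULL`, the median
#'   `||accel||` over the recording is used.
#' @return a list with `values` (named numeric 4-vector) and `imputed`
#'   (logical 4-vector).
#' @export
movement_features <- function(imu, positions, epoch, grid, gravity = NULL) {
  b <- epoch_bounds(grid, epoch)
  fs <- imu$sample_rate
  t0 <- imu$t[1]
  n <- length(imu$t)
  ## half-open [start, end): sample i covers time t0 + (i-1)/fs; the small
  ## epsilon guards against sample rates inferred with rounding error
  i0 <- max(1L, as.integer(floor((b["start"] - t0) * fs + 1e-6)) + 1L)
  i1 <- min(n, as.integer(floor((b["end"] - t0) * fs - 1e-6)) + 1L)
  if (i1 < i0) {
    values <- c(NA_real_, NA_real_, NA_real_, NA_real_)
    names(values) <- movement_feature_names
    return(list(values = values, imputed = rep(TRUE, 4L)))
  }
  idx <- i0:i1
  if (is.null(gravity))
    gravity <- stats::median(sqrt(rowSums(imu$accel^2)))
  labs <- as.integer(positions$labels[idx])
  counts <- tabulate(labs, nbins = length(position_levels))
  dominant <- which.max(counts)                     # ties: earlier label order
  changes <- sum(diff(labs) != 0L)
  an <- sqrt(rowSums(imu$accel[idx, , drop = FALSE]^2))
  gn <- sqrt(rowSums(imu$gyro[idx, , drop = FALSE]^2))
  values <- c(dominant, changes, mean(abs(an - gravity)), mean(gn))
  names(values) <- movement_feature_names
  list(values = values, imputed = rep(FALSE, 4L))
}
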