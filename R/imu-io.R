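#' IMU recording container
#'
#' A 6-axis inertial stream: 3-axis accelerometer (specific force, m/s^2 by
#' default) and 3-axis gyroscope (rad/s), uniformly sampled.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param accel n x 3 numeric matrix of accelerations.
#' @param gyro n x 3 numeric matrix of angular velocities.
#' @param sample_rate sampling rate in Hz; inferred from `t` when `NULL`.
#' @param accel_units `"m/s^2"` or `"g"`; metadata only.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(t, accel, gyro, sample_rate = NULL, accel_units = "m/s^2") {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    abort_argument("`accel` and `gyro` must have 3 columns")
  if (nrow(accel) != nrow(gyro) || nrow(accel) != length(t))
    abort_argument("`t`, `accel` and `gyro` must have equal length")
  if (length(t) < 2L)
    abort_argument("an IMU recording needs at least 2 samples")
  if (any(diff(t) <= 0))
    abort_data("IMU timestamps must be strictly increasing")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(t))
  if (sample_rate <= 0)
    abort_argument("`sample_rate` must be positive")
  structure(
    list(t = as.numeric(t), accel = accel, gyro = gyro,
         sample_rate = as.numeric(sample_rate), accel_units = accel_units),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %.1f Hz (%.1f s)\n",
              length(x$t), x$sample_rate, duration(x)))
  invisible(x)
}

#' @export
duration.imu_recording <- function(x) length(x$t) / x$sample_rate

imu_columns <- c("t", "ax", "ay", "az", "gx", "gy", "gz")

#' Read an IMU CSV file
#'
#' Expects a header `t,ax,ay,az,gx,gy,gz` with timestamps in seconds.
#' The sample rate is inferred from the median timestamp increment.
#'
#' @param path path to the CSV file.
#' @return an [imu_recording()].
#' @export
read_imu <- function(path) {
  if (!file.exists(path))
    abort_format(sprintf("IMU file not found: %s", path))
  d <- utils::read.csv(path)
  missing <- setdiff(imu_columns, names(d))
  if (length(missing))
    abort_format(sprintf("IMU file %s lacks column(s): %s", path,
                         paste(missing, collapse = ", ")))
  if (any(diff(d$t) <= 0))
    abort_data(sprintf("non-monotone timestamps in IMU file: %s", path))
  imu_recording(d$t, as.matrix(d[, c("ax", "ay", "az")]),
                as.matrix(d[, c("gx", "gy", "gz")]))
}

#' Write an IMU recording as CSV
#' @param imu an [imu_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imu <- function(imu, path) {
  stopifnot(inherits(imu, "imu_recording"))
  d <- data.frame(t = imu$t, ax = imu$accel[, 1], ay = imu$accel[, 2],
                  az = imu$accel[, 3], gx = imu$gyro[, 1], gy = imu$gyro[, 2],
                  gz = imu$gyro[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
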