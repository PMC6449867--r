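## helpers: quaternion from axis-angle, static IMU construction
quat_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

static_imu <- function(accel_row, secs = 60, fs = 250) {
  n <- secs * fs
  imu_recording((0:(n - 1)) / fs,
                matrix(accel_row, n, 3, byrow = TRUE),
                matrix(0, n, 3))
}

## angle (deg) between estimated and expected gravity direction
gravity_error_deg <- function(q_row, g_true) {
  w <- q_row[1]; x <- q_row[2]; y <- q_row[3]; z <- q_row[4]
  g <- c(-2 * (x * z - w * y), -2 * (w * x + y * z), -(1 - 2 * (x^2 + y^2)))
  acos(max(-1, min(1, sum(g * g_true) / sqrt(sum(g_true^2))))) * 180 / pi
}

test_that("a static level sensor holds the identity orientation", {
  imu <- static_imu(c(0, 0, 9.81))
  o <- madgwick_fuse(imu, beta = 0.1, q0 = c(1, 0, 0, 0))
  qf <- o$quaternions[nrow(o$quaternions), ]
  ang <- 2 * acos(min(1, abs(qf[1]))) * 180 / pi
  expect_lt(ang, 0.5)
  ## unit norm preserved throughout
  norms <- sqrt(rowSums(o$quaternions^2))
  expect_lt(max(abs(norms - 1)), 1e-6)
})

test_that("constant yaw rate about gravity integrates to the turned angle", {
  fs <- 250; secs <- 9
  n <- fs * secs
  rate <- 10 * pi / 180                       # 10 deg/s about z
  imu <- imu_recording((0:(n - 1)) / fs,
                       matrix(c(0, 0, 9.81), n, 3, byrow = TRUE),
                       cbind(0, 0, rep(rate, n)))
  o <- madgwick_fuse(imu, beta = 0.1)
  qf <- unname(o$quaternions[n, ])
  yaw <- atan2(2 * (qf[1] * qf[4] + qf[2] * qf[3]),
               1 - 2 * (qf[3]^2 + qf[4]^2)) * 180 / pi
  expect_equal(abs(yaw), 90, tolerance = 2)
})

test_that("a tilted static sensor converges to the measured gravity direction", {
  accel <- c(3, 4, 8)                          # arbitrary tilt
  imu <- static_imu(accel, secs = 30)
  ## start from a clearly wrong orientation
  o <- madgwick_fuse(imu, beta = 0.1,
                     q0 = quat_axis_angle(c(0, 1, 0), pi / 2))
  err <- gravity_error_deg(o$quaternions[nrow(o$quaternions), ], -accel)
  expect_lt(err, 1)
})

test_that("zero-norm accelerometer samples fall back to gyro-only updates", {
  n <- 250
  imu <- imu_recording((0:(n - 1)) / 250, matrix(0, n, 3), matrix(0, n, 3))
  o <- madgwick_fuse(imu)
  expect_equal(o$quaternions[n, ], c(1, 0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("position classification follows the mounting convention", {
  ## identity: gravity along sensor -z -> supine
  expect_equal(as.character(classify_position(c(1, 0, 0, 0))), "supine")
  ## 90 degree roll about y: gravity moves to +/- x -> left / right
  q_roll <- quat_axis_angle(c(0, 1, 0), pi / 2)
  lab <- as.character(classify_position(q_roll))
  expect_true(lab %in% c("left", "right"))
  q_roll2 <- quat_axis_angle(c(0, 1, 0), -pi / 2)
  lab2 <- as.character(classify_position(q_roll2))
  expect_true(lab2 %in% c("left", "right"))
  expect_false(lab == lab2)
  ## near the 45-degree sector boundary the label never jumps to an
  ## unrelated position, and crossing it flips between the two neighbors
  q_in <- quat_axis_angle(c(0, 1, 0), pi / 4 - 0.01)
  q_out <- quat_axis_angle(c(0, 1, 0), pi / 4 + 0.01)
  expect_equal(as.character(classify_position(q_in)), "supine")
  expect_true(as.character(classify_position(q_out)) %in% c("left", "right"))
  ## an exact score tie resolves by the priority order (supine first)
  tied <- default_mounting()
  tied$left <- tied$supine
  expect_equal(as.character(classify_position(c(1, 0, 0, 0), tied)), "supine")
})

test_that("position classification is invariant to yaw", {
  set.seed(41)
  qmul <- function(a, b) c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  for (trial in 1:20) {
    q <- quat_axis_angle(rnorm(3), runif(1, 0, pi))
    base <- as.character(classify_position(q))
    ## rotating about the earth gravity axis must not change the label:
    ## gravity in sensor frame depends on q only through the sensor-frame
    ## gravity vector, so compose with a rotation about that vector
    gdir <- -c(2 * (q[2] * q[4] - q[1] * q[3]),
               2 * (q[1] * q[2] + q[3] * q[4]),
               1 - 2 * (q[2]^2 + q[3]^2))
    yawed <- qmul(q, quat_axis_angle(gdir, runif(1, 0, 2 * pi)))
    expect_equal(as.character(classify_position(yawed)), base)
  }
})

test_that("the position timeline suppresses sub-hysteresis jitter", {
  n <- 200
  q <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  ## 3-sample flip to prone in the middle: absorbed by 5-sample hysteresis
  q_pr <- quat_axis_angle(c(0, 1, 0), pi)
  q[100:102, ] <- matrix(q_pr, 3, 4, byrow = TRUE)
  o <- structure(list(quaternions = q, sample_rate = 250,
                      t = (0:(n - 1)) / 250), class = "orientation_series")
  pos <- position_timeline(o, hysteresis_samples = 5L)
  expect_equal(length(pos$change_times), 0L)
  expect_true(all(pos$labels == "supine"))
  ## a long flip is kept
  q[100:180, ] <- matrix(q_pr, 81, 4, byrow = TRUE)
  o2 <- structure(list(quaternions = q, sample_rate = 250,
                       t = (0:(n - 1)) / 250), class = "orientation_series")
  pos2 <- position_timeline(o2, hysteresis_samples = 5L)
  expect_equal(length(pos2$change_times), 2L)
})

test_that("movement features read position, changes and activity per epoch", {
  fs <- 250; n <- 60 * fs
  imu <- imu_recording((0:(n - 1)) / fs,
                       matrix(c(0, 0, 9.81), n, 3, byrow = TRUE),
                       matrix(0, n, 3))
  o <- madgwick_fuse(imu)
  pos <- position_timeline(o)
  grid <- epoch_grid(2)
  f <- movement_features(imu, pos, 0, grid)
  expect_equal(unname(f$values["move_position"]), 1)      # supine
  expect_equal(unname(f$values["move_changes"]), 0)
  expect_lt(unname(f$values["move_accel"]), 0.01)
  expect_lt(unname(f$values["move_gyro"]), 0.01)

  ## add a burst in epoch 1: its activity must exceed the static epoch
  imu2 <- imu
  idx <- (30 * fs):(32 * fs)
  imu2$accel[idx, ] <- imu2$accel[idx, ] + rnorm(3 * length(idx), 0, 2)
  f_static <- movement_features(imu2, pos, 0, grid)
  f_burst <- movement_features(imu2, pos, 1, grid)
  expect_gt(unname(f_burst$values["move_accel"]),
            unname(f_static$values["move_accel"]))
})

test_that("position-change counts equal the run-length oracle", {
  set.seed(42)
  fs <- 10                                     # coarse labels are enough here
  for (trial in 1:20) {
    n_ep <- 4
    labs <- sample(position_levels, n_ep * 30 * fs, replace = TRUE,
                   prob = c(0.9, 0.04, 0.03, 0.02, 0.01))
    pos <- structure(list(labels = factor(labs, levels = position_levels),
                          change_times = numeric(0), sample_rate = fs,
                          t = (seq_along(labs) - 1) / fs),
                     class = "position_series")
    n <- length(labs)
    imu <- imu_recording((0:(n - 1)) / fs, matrix(c(0, 0, 9.81), n, 3, byrow = TRUE),
                         matrix(0, n, 3))
    grid <- epoch_grid(n_ep)
    for (k in 0:(n_ep - 1)) {
      f <- movement_features(imu, pos, k, grid)
      seg <- labs[(k * 30 * fs + 1):((k + 1) * 30 * fs)]
      expect_equal(unname(f$values["move_changes"]),
                   length(rle(seg)$lengths) - 1L)
    }
  }
})
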