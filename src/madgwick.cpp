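#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Madgwick gradient-descent orientation filter, IMU variant (gyroscope +
// accelerometer, no magnetometer). The quaternion state q describes the
// earth frame relative to the sensor frame; the gradient step pulls the
// predicted gravity direction toward the (normalized) accelerometer
// measurement with gain beta (rad/s), blended into gyroscope quaternion
// integration. A zero-norm accelerometer sample degrades gracefully to a
// gyro-only update for that step.
// [[Rcpp::export]]
NumericMatrix madgwick_fuse_cpp(NumericMatrix accel, NumericMatrix gyro,
                                double dt, double beta, NumericVector q0) {
  const int n = accel.nrow();
  NumericMatrix out(n, 4);
  double q1 = q0[0], q2 = q0[1], q3 = q0[2], q4 = q0[3];

  for (int t = 0; t < n; ++t) {
    const double gx = gyro(t, 0), gy = gyro(t, 1), gz = gyro(t, 2);
    double ax = accel(t, 0), ay = accel(t, 1), az = accel(t, 2);

    // rate of change from gyroscope: qDot = 0.5 * q (x) (0, gx, gy, gz)
    double qDot1 = 0.5 * (-q2 * gx - q3 * gy - q4 * gz);
    double qDot2 = 0.5 * ( q1 * gx + q3 * gz - q4 * gy);
    double qDot3 = 0.5 * ( q1 * gy - q2 * gz + q4 * gx);
    double qDot4 = 0.5 * ( q1 * gz + q2 * gy - q3 * gx);

    const double anorm = std::sqrt(ax * ax + ay * ay + az * az);
    if (anorm > 0.0) {
      ax /= anorm; ay /= anorm; az /= anorm;

      const double _2q1 = 2.0 * q1, _2q2 = 2.0 * q2;
      const double _2q3 = 2.0 * q3, _2q4 = 2.0 * q4;
      const double _4q1 = 4.0 * q1, _4q2 = 4.0 * q2, _4q3 = 4.0 * q3;
      const double _8q2 = 8.0 * q2, _8q3 = 8.0 * q3;
      const double q1q1 = q1 * q1, q2q2 = q2 * q2;
      const double q3q3 = q3 * q3, q4q4 = q4 * q4;

      // gradient of the gravity-alignment objective (J^T f)
      double s1 = _4q1 * q3q3 + _2q3 * ax + _4q1 * q2q2 - _2q2 * ay;
      double s2 = _4q2 * q4q4 - _2q4 * ax + 4.0 * q1q1 * q2 - _2q1 * ay
                  - _4q2 + _8q2 * q2q2 + _8q2 * q3q3 + _4q2 * az;
      double s3 = 4.0 * q1q1 * q3 + _2q1 * ax + _4q3 * q4q4 - _2q4 * ay
                  - _4q3 + _8q3 * q2q2 + _8q3 * q3q3 + _4q3 * az;
      double s4 = 4.0 * q2q2 * q4 - _2q2 * ax + 4.0 * q3q3 * q4 - _2q3 * ay;
      const double snorm = std::sqrt(s1 * s1 + s2 * s2 + s3 * s3 + s4 * s4);
      if (snorm > 0.0) {
        s1 /= snorm; s2 /= snorm; s3 /= snorm; s4 /= snorm;
        qDot1 -= beta * s1;
        qDot2 -= beta * s2;
        qDot3 -= beta * s3;
        qDot4 -= beta * s4;
      }
    }

    q1 += qDot1 * dt;
    q2 += qDot2 * dt;
    q3 += qDot3 * dt;
    q4 += qDot4 * dt;
    const double qnorm = std::sqrt(q1 * q1 + q2 * q2 + q3 * q3 + q4 * q4);
    q1 /= qnorm; q2 /= qnorm; q3 /= qnorm; q4 /= qnorm;

    out(t, 0) = q1; out(t, 1) = q2; out(t, 2) = q3; out(t, 3) = q4;
  }
  return out;
}
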