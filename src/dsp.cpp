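// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Linear-phase FIR filtering by FFT overlap-add with group-delay
// compensation (net zero phase for the symmetric designs used here).
// Returns a vector of the input length.
// [[Rcpp::export]]
arma::vec fir_filter_cpp(const arma::vec& x, const arma::vec& b) {
  const uword lb = b.n_elem, n = x.n_elem;
  const uword delay = (lb - 1) / 2;
  const uword full_len = n + lb - 1;
  uword B = 65536;
  while (B < 4 * lb) B <<= 1;
  if (B > 2 * full_len) { B = 1; while (B < full_len) B <<= 1; }
  const uword step = B - lb + 1;

  vec bp(B, fill::zeros);
  bp.head(lb) = b;
  const cx_vec Bf = fft(bp);

  vec acc(full_len + B, fill::zeros);
  vec seg(B);
  for (uword pos = 0; pos < n; pos += step) {
    const uword len = std::min(step, n - pos);
    seg.zeros();
    seg.head(len) = x.subvec(pos, pos + len - 1);
    const vec y = real(ifft(fft(seg) % Bf));
    acc.subvec(pos, pos + B - 1) += y;
  }
  return acc.subvec(delay, delay + n - 1);
}

// Short-time spectral subtraction: Hann-windowed frames (hop = frame/2),
// per-bin magnitude reduced by alpha * template and floored at
// floor_frac * magnitude, phase kept, overlap-add reconstruction.
// With hop = frame/2 the periodic Hann windows sum to exactly 1, so a
// zero template and alpha = 0 give an identity up to rounding.
// [[Rcpp::export]]
arma::vec spectral_subtract_cpp(const arma::vec& x, const arma::vec& tmpl,
                                double alpha, double floor_frac) {
  const uword frame = tmpl.n_elem;
  const uword hop = frame / 2;
  const uword n = x.n_elem;
  const uword total = ((n + frame - 1) / frame + 2) * frame + hop;

  vec xp(total, fill::zeros);
  xp.subvec(hop, hop + n - 1) = x;
  vec w(frame);
  for (uword i = 0; i < frame; ++i)
    w[i] = 0.5 * (1.0 - std::cos(2.0 * M_PI * double(i) / double(frame)));
  const vec at = alpha * tmpl;

  vec y(total, fill::zeros);
  const uword half = frame / 2;
  for (uword s = 0; s + frame <= total; s += hop) {
    cx_vec X = fft(xp.subvec(s, s + frame - 1) % w);
    // gain is symmetric in the bin index; compute half, mirror the rest
    for (uword k = 0; k <= half; ++k) {
      const double m = std::abs(X[k]);
      double g = m - at[k];
      const double flo = floor_frac * m;
      if (g < flo) g = flo;
      const double scale = m > 0.0 ? g / m : 0.0;
      X[k] *= scale;
      if (k > 0 && k < half) X[frame - k] *= scale;
    }
    y.subvec(s, s + frame - 1) += real(ifft(X));
  }
  return y.subvec(hop, hop + n - 1);
}
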