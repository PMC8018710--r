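#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Passive-map fast path: per pixel, steer the channel records to the pixel
// with windowed-sinc fractional delays, form the time-domain correlation
// matrix, and evaluate either the robust Capon power (eigendecomposition +
// Lagrange-multiplier root find) or the conventional delay-sum-square power.
// The interpolation kernel (Hann-windowed sinc, `taps` points) matches the
// R reference implementation in steer_signals() exactly.

static inline double sinc(double x) {
  if (std::abs(x) < 1e-12) return 1.0;
  const double px = M_PI * x;
  return std::sin(px) / px;
}

// Steer one channel: out[j] = s(j + tau), tau in samples; Hann-windowed
// sinc. The kernel is shift-invariant: with i0 = floor(tau) and
// f = tau - i0, sample j draws on source indices j + i0 - taps/2 + 1 + off
// with weights depending only on f, so the taps weights are computed once
// and applied as an FIR filter.
static void steer_channel(const double* s, int n, double tau, int taps,
                          double* out) {
  const double half = taps / 2.0;
  const int i0 = (int)std::floor(tau);
  const double f = tau - i0;
  std::vector<double> w(taps);
  for (int off = 0; off < taps; ++off) {
    const double x = f + taps / 2 - 1 - off;   // = p - k, constant in j
    w[off] = sinc(x) * 0.5 * (1.0 + std::cos(M_PI * x / half));
  }
  const int base = i0 - taps / 2 + 1;
  for (int j = 0; j < n; ++j) {
    const int k0 = j + base;
    const int lo = std::max(0, -k0), hi = std::min(taps, n - k0);
    double acc = 0.0;
    for (int off = lo; off < hi; ++off) acc += w[off] * s[k0 + off];
    out[j] = acc;
  }
}

// Monotone constraint function of the robust Capon Lagrange multiplier:
// g(lambda) = sum z_i^2 / (1 + lambda gamma_i)^2.
static double g_of_lambda(const arma::vec& gam, const arma::vec& z2,
                          double lambda) {
  double s = 0.0;
  for (arma::uword i = 0; i < gam.n_elem; ++i) {
    const double d = 1.0 + lambda * gam[i];
    s += z2[i] / (d * d);
  }
  return s;
}

// Robust Capon power kernel a_hat' R^{-1} a_hat for eigenvalues gam and
// nominal-vector eigen-coordinates z = U' a_bar.
static double rcb_kernel(const arma::vec& gam, const arma::vec& z,
                         double epsilon) {
  const arma::vec z2 = arma::square(z);
  double lo = 0.0, hi = 1.0 / std::max(epsilon * gam.max(), 1e-300);
  if (hi < 1.0) hi = 1.0;
  int it = 0;
  while (g_of_lambda(gam, z2, hi) > epsilon && it++ < 200) hi *= 10.0;
  if (it >= 200) Rcpp::stop("robust Capon multiplier root not bracketed");
  for (int i = 0; i < 200; ++i) {
    const double mid = 0.5 * (lo + hi);
    if (g_of_lambda(gam, z2, mid) > epsilon) lo = mid; else hi = mid;
  }
  const double lambda = 0.5 * (lo + hi);
  double kern = 0.0;
  for (arma::uword i = 0; i < gam.n_elem; ++i) {
    const double d = 1.0 + lambda * gam[i];
    kern += lambda * lambda * gam[i] * z2[i] / (d * d);
  }
  return kern;
}

// [[Rcpp::export]]
arma::mat pam_map_cpp(const arma::mat& samples, const double fs,
                      const arma::mat& elem_pos, const arma::vec& gx,
                      const arma::vec& gz, const double c, const double rho,
                      const double epsilon, const double loading,
                      const int range_exponent, const bool das,
                      const int taps) {
  const arma::uword N = samples.n_rows, T = samples.n_cols;
  const arma::uword nx = gx.n_elem, nz = gz.n_elem;
  const double dt = 1.0 / fs, TH = T / fs;
  arma::mat power(nx, nz, arma::fill::zeros);
  if (arma::accu(arma::square(samples)) <= 0.0)
    return power;  // all-zero record -> all-zero map
  const arma::mat st = samples.t();  // T x N, channels contiguous
  arma::mat S(T, N);
  arma::vec d(N), gam, z;
  arma::mat C, U;
  const arma::vec abar = arma::ones<arma::vec>(N);
  for (arma::uword iz = 0; iz < nz; ++iz) {
    for (arma::uword ix = 0; ix < nx; ++ix) {
      for (arma::uword n = 0; n < N; ++n) {
        const double dx = elem_pos(n, 0) - gx[ix];
        const double dy = elem_pos(n, 1);
        const double dz = elem_pos(n, 2) - gz[iz];
        d[n] = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      const double dmin = d.min(), dbar = arma::mean(d);
      const double pref = 4.0 * M_PI * std::pow(dbar, range_exponent) /
        (TH * rho * c);
      for (arma::uword n = 0; n < N; ++n)
        steer_channel(st.colptr(n), (int)T, (d[n] - dmin) / c * fs, taps,
                      S.colptr(n));
      if (das) {
        const arma::vec beam = arma::mean(S, 1);
        power(ix, iz) = pref * arma::accu(arma::square(beam)) * dt;
      } else {
        C = S.t() * S * dt;
        const double tr = arma::trace(C);
        if (tr <= 0.0) { power(ix, iz) = 0.0; continue; }
        C.diag() += loading * tr / N;
        if (!arma::eig_sym(gam, U, C))
          Rcpp::stop("eigendecomposition failed at pixel (%d, %d)",
                     (int)ix + 1, (int)iz + 1);
        gam.clamp(0.0, arma::datum::inf);
        z = U.t() * abar;
        const double kern = rcb_kernel(gam, z, epsilon);
        power(ix, iz) = kern > 0.0 ? pref / kern : 0.0;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return power;
}
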