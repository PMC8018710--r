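#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Rayleigh-Sommerfeld summation: sum over aperture points of
// area * exp(i k R) / R at each field point. Source points with R below
// 1e-9 m (coincident with a field point) are guarded by exclusion.
// [[Rcpp::export]]
arma::cx_vec rs_sum_cpp(const arma::mat& src, const arma::vec& areas,
                        const arma::mat& fld, const double k) {
  const arma::uword ns = src.n_rows, nf = fld.n_rows;
  arma::cx_vec out(nf, arma::fill::zeros);
  const double* sx = src.colptr(0);
  const double* sy = src.colptr(1);
  const double* sz = src.colptr(2);
  for (arma::uword j = 0; j < nf; ++j) {
    const double fx = fld(j, 0), fy = fld(j, 1), fz = fld(j, 2);
    double re = 0.0, im = 0.0;
    for (arma::uword i = 0; i < ns; ++i) {
      const double dx = fx - sx[i], dy = fy - sy[i], dz = fz - sz[i];
      const double R = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (R < 1e-9) continue;
      const double w = areas[i] / R, ph = k * R;
      re += w * std::cos(ph);
      im += w * std::sin(ph);
    }
    out[j] = std::complex<double>(re, im);
  }
  return out;
}
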