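#include <Rcpp.h>
using namespace Rcpp;

// Bilinear gather used by the plane-constrained volume resampler.
// m: (n_orth x n1*n2) volume arranged with the transform plane flattened
// into columns; (u, v) fractional 1-based source coordinates per output
// pixel. Out-of-bounds samples contribute 0.
// [[Rcpp::export(name = ".gather_bilinear_cpp")]]
NumericMatrix gather_bilinear_cpp(NumericMatrix m, int n1, int n2,
                                  NumericVector u, NumericVector v) {
  const int n_orth = m.nrow();
  const R_xlen_t npix = u.size();
  NumericMatrix out(n_orth, npix);
  for (R_xlen_t p = 0; p < npix; ++p) {
    const double uu = u[p], vv = v[p];
    const int u0 = (int)std::floor(uu), v0 = (int)std::floor(vv);
    const double fu = uu - u0, fv = vv - v0;
    const double w[4] = {(1 - fu) * (1 - fv), fu * (1 - fv),
                         (1 - fu) * fv, fu * fv};
    const int ju[4] = {u0, u0 + 1, u0, u0 + 1};
    const int jv[4] = {v0, v0, v0 + 1, v0 + 1};
    double *col = &out(0, p);
    for (int c = 0; c < 4; ++c) {
      if (w[c] <= 0 || ju[c] < 1 || ju[c] > n1 || jv[c] < 1 || jv[c] > n2)
        continue;
      const double wc = w[c];
      const double *src = &m(0, (R_xlen_t)(ju[c] - 1) +
                                    (R_xlen_t)(jv[c] - 1) * n1);
      for (int i = 0; i < n_orth; ++i) col[i] += wc * src[i];
    }
  }
  return out;
}

// Nearest-neighbour variant (exact for integer-voxel shifts).
// [[Rcpp::export(name = ".gather_nearest_cpp")]]
NumericMatrix gather_nearest_cpp(NumericMatrix m, int n1, int n2,
                                 NumericVector u, NumericVector v) {
  const int n_orth = m.nrow();
  const R_xlen_t npix = u.size();
  NumericMatrix out(n_orth, npix);
  for (R_xlen_t p = 0; p < npix; ++p) {
    const int a = (int)std::lround(u[p]), b = (int)std::lround(v[p]);
    if (a < 1 || a > n1 || b < 1 || b > n2) continue;
    const double *src = &m(0, (R_xlen_t)(a - 1) + (R_xlen_t)(b - 1) * n1);
    double *col = &out(0, p);
    for (int i = 0; i < n_orth; ++i) col[i] = src[i];
  }
  return out;
}
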