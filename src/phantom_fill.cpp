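#include <Rcpp.h>
using namespace Rcpp;

// Voxelise the posed half-ellipsoid shell analytically: for every voxel
// centre, invert the pose (u = R^-1 (p - T) / s) and test the shell
// condition between the outer and inner ellipsoids, cut at the ventral
// extent. Additive Gaussian noise is drawn from R's RNG (so the phantom is
// reproducible under set.seed), clipped to the bit range.
// [[Rcpp::export(name = ".phantom_fill_cpp")]]
IntegerVector phantom_fill_cpp(IntegerVector dims, NumericVector center,
                               NumericVector tr, NumericMatrix Rinv,
                               double s, double a, double b, double cc,
                               double a_in, double b_in, double c_in,
                               double ve, double bone, double bg,
                               double noise_sd, double maxval) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const double amax = ve * a;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double pz = (k + 1) - center[2] - tr[2];
    for (int j = 0; j < ny; ++j) {
      const double py = (j + 1) - center[1] - tr[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double px = (i + 1) - center[0] - tr[0];
        const double ux = (Rinv(0, 0) * px + Rinv(0, 1) * py +
                           Rinv(0, 2) * pz) / s;
        const double uy = (Rinv(1, 0) * px + Rinv(1, 1) * py +
                           Rinv(1, 2) * pz) / s;
        const double uz = (Rinv(2, 0) * px + Rinv(2, 1) * py +
                           Rinv(2, 2) * pz) / s;
        const double q_out = (ux / a) * (ux / a) + (uy / b) * (uy / b) +
          (uz / cc) * (uz / cc);
        const double q_in = (ux / a_in) * (ux / a_in) +
          (uy / b_in) * (uy / b_in) + (uz / c_in) * (uz / c_in);
        double val = (q_out <= 1 && q_in >= 1 && ux <= amax) ? bone : bg;
        if (noise_sd > 0) val += noise_sd * norm_rand();
        val = std::nearbyint(val);
        if (val < 0) val = 0;
        if (val > maxval) val = maxval;
        out[idx] = (int)val;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
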