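#include <Rcpp.h>
using namespace Rcpp;

// Round a numeric array to integers in one pass, preserving dim.
// [[Rcpp::export(name = ".round_to_int_cpp")]]
IntegerVector round_to_int_cpp(NumericVector x) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = (int)std::nearbyint(x[i]);
  out.attr("dim") = x.attr("dim");
  return out;
}

// 16-bit -> 8-bit min-max rescale with half-up rounding, one pass.
// [[Rcpp::export(name = ".rescale_8bit_cpp")]]
IntegerVector rescale_8bit_cpp(IntegerVector x, double lo, double hi) {
  IntegerVector out(x.size());
  const double f = 255.0 / (hi - lo);
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = (int)std::floor((x[i] - lo) * f + 0.5);
  out.attr("dim") = x.attr("dim");
  return out;
}
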