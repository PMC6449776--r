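#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Separable convolution of a 3-D array along one axis (1, 2 or 3) with a
// symmetric unit-sum kernel, half-sample symmetric ("reflect") boundaries.
// Reflection keeps the implied convolution matrix doubly stochastic, so the
// global sum is conserved exactly for a unit-sum kernel.
// [[Rcpp::export(name = ".convolveAxis3d")]]
NumericVector convolveAxis3d(NumericVector arr, IntegerVector dims,
                             NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (arr.size() != n) stop("array length does not match dims");
  const int L = kernel.size();
  const int r = (L - 1) / 2;
  if (L % 2 == 0) stop("kernel must have odd length");
  int nAxis = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  if (r >= nAxis) stop("kernel radius too large for axis");

  // reflected index lookup for positions -r .. nAxis-1+r
  std::vector<int> refl(nAxis + 2 * r);
  for (int p = -r; p < nAxis + r; ++p) {
    int q = p;
    if (q < 0) q = -q - 1;            // half-sample reflection
    if (q >= nAxis) q = 2 * nAxis - 1 - q;
    refl[p + r] = q;
  }

  NumericVector out(n);
  R_xlen_t strideAxis = (axis == 1) ? 1 : (axis == 2) ? nx
                                                      : (R_xlen_t)nx * ny;
  // iterate over all lines along the chosen axis
  int nOuter1, nOuter2;
  R_xlen_t stride1, stride2;
  if (axis == 1) {
    nOuter1 = ny; stride1 = nx;
    nOuter2 = nz; stride2 = (R_xlen_t)nx * ny;
  } else if (axis == 2) {
    nOuter1 = nx; stride1 = 1;
    nOuter2 = nz; stride2 = (R_xlen_t)nx * ny;
  } else {
    nOuter1 = nx; stride1 = 1;
    nOuter2 = ny; stride2 = nx;
  }
  std::vector<double> line(nAxis + 2 * r);
  for (int o2 = 0; o2 < nOuter2; ++o2) {
    for (int o1 = 0; o1 < nOuter1; ++o1) {
      R_xlen_t base = o1 * stride1 + o2 * stride2;
      for (int p = 0; p < nAxis + 2 * r; ++p)
        line[p] = arr[base + refl[p] * strideAxis];
      for (int i = 0; i < nAxis; ++i) {
        double acc = 0.0;
        for (int j = 0; j < L; ++j) acc += kernel[j] * line[i + j];
        out[base + (R_xlen_t)i * strideAxis] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
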