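#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labelling of a 3-D logical array under 6-, 18- or
// 26-neighbour connectivity. Returns an integer array of the same shape with
// components numbered from 1 (0 = background).
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims,
                      int connectivity = 18) {
  if (dims.size() != 3)
    stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n)
    stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++current;
    labels[idx] = current;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
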