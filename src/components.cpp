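#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D (or 2D, nz = 1) binary array by
// breadth-first search. `connectivity` is 6, 18 or 26 in 3D; for a single
// slice 26 degenerates to 8-connectivity and 6 to 4-connectivity.

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector img, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!img[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (static_cast<R_xlen_t>(nx) * ny);
      for (const auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t u = xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz);
        if (img[u] && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  if (dims.size() > 2)
    lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  else
    lab.attr("dim") = IntegerVector::create(nx, ny);
  return lab;
}
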