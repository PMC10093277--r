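#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling of a binary mask by iterative flood fill.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
// [[Rcpp::export]]
IntegerVector cc_label_3d(const IntegerVector& mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        if (connectivity != 6 && connectivity != 18 && connectivity != 26)
          stop("connectivity must be 6, 18 or 26");
        offs.push_back({dx, dy, dz});
      }

  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      int rem = (int)(idx % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (const auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[j] != 0 && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}
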