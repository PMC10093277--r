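// Texture-matrix accumulation for the radiomics extractor. Input is an
// integer grid with 0 outside the ROI and discretised gray levels 1..Ng
// inside. All matrices use merged-direction aggregation over the 26- (GLCM,
// GLDM, NGTDM) or 13- (GLRLM) neighbourhood.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static std::vector<std::array<int, 3>> all_offsets() {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) offs.push_back({dx, dy, dz});
  return offs;
}

static inline int grid_at(const IntegerVector& g, int nx, int ny, int nz,
                          int x, int y, int z) {
  if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
  return g[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
}

// Gray-level co-occurrence matrix summed over all 26 offsets (symmetric).
// [[Rcpp::export]]
NumericMatrix glcm_3d(const IntegerVector& grid, int ng) {
  IntegerVector d = grid.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericMatrix M(ng, ng);
  auto offs = all_offsets();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int gi = grid_at(grid, nx, ny, nz, x, y, z);
        if (!gi) continue;
        for (const auto& o : offs) {
          int gj = grid_at(grid, nx, ny, nz, x + o[0], y + o[1], z + o[2]);
          if (gj) M(gi - 1, gj - 1) += 1.0;
        }
      }
  return M;
}

// Gray-level run-length matrix over the 13 unique directions.
// [[Rcpp::export]]
NumericMatrix glrlm_3d(const IntegerVector& grid, int ng) {
  IntegerVector d = grid.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int max_run = std::max(std::max(nx, ny), nz);
  NumericMatrix M(ng, max_run);
  auto offs = all_offsets();
  // keep the 13 directions whose first nonzero component is positive
  for (const auto& o : offs) {
    if (o[2] < 0) continue;
    if (o[2] == 0 && o[1] < 0) continue;
    if (o[2] == 0 && o[1] == 0 && o[0] < 0) continue;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int gi = grid_at(grid, nx, ny, nz, x, y, z);
          if (!gi) continue;
          // run start: predecessor along -o differs
          if (grid_at(grid, nx, ny, nz, x - o[0], y - o[1], z - o[2]) == gi)
            continue;
          int len = 1;
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          while (grid_at(grid, nx, ny, nz, xx, yy, zz) == gi) {
            ++len; xx += o[0]; yy += o[1]; zz += o[2];
          }
          M(gi - 1, len - 1) += 1.0;
        }
  }
  return M;
}

// Gray-level dependence matrix: column j+1 counts voxels with exactly j
// neighbours (26-neighbourhood) inside the ROI within alpha gray levels.
// [[Rcpp::export]]
NumericMatrix gldm_3d(const IntegerVector& grid, int ng, int alpha) {
  IntegerVector d = grid.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericMatrix M(ng, 27);
  auto offs = all_offsets();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int gi = grid_at(grid, nx, ny, nz, x, y, z);
        if (!gi) continue;
        int dep = 0;
        for (const auto& o : offs) {
          int gj = grid_at(grid, nx, ny, nz, x + o[0], y + o[1], z + o[2]);
          if (gj && std::abs(gj - gi) <= alpha) ++dep;
        }
        M(gi - 1, dep) += 1.0;
      }
  return M;
}

// Neighbourhood gray-tone difference: per gray level, voxel count n_i and
// accumulated |level - mean(valid neighbours)| s_i.
// [[Rcpp::export]]
List ngtdm_3d(const IntegerVector& grid, int ng) {
  IntegerVector d = grid.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector n(ng), s(ng);
  auto offs = all_offsets();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int gi = grid_at(grid, nx, ny, nz, x, y, z);
        if (!gi) continue;
        double sum = 0; int cnt = 0;
        for (const auto& o : offs) {
          int gj = grid_at(grid, nx, ny, nz, x + o[0], y + o[1], z + o[2]);
          if (gj) { sum += gj; ++cnt; }
        }
        n[gi - 1] += 1;
        if (cnt > 0) s[gi - 1] += std::fabs(gi - sum / cnt);
      }
  return List::create(_["n"] = n, _["s"] = s);
}
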