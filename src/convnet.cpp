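// Minimal 3D conv-net kernels: 3x3x3 same-padding convolution via
// im2col + BLAS gemm, 2x2x2 max pooling, and nearest x2 upsampling.
// Volumes are channel-last R arrays with dim (nx, ny, nz, C).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col3(const double* x, int nx, int ny, int nz, int C) {
  const arma::uword N = (arma::uword)nx * ny * nz;
  arma::mat M(27 * (arma::uword)C, N, arma::fill::zeros);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t volsz = plane * nz;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)c * volsz;
    int koff = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++koff) {
          const arma::uword row = (arma::uword)koff * C + c;
          for (int z = 0; z < nz; ++z) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              R_xlen_t src = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx;
              arma::uword col0 = (arma::uword)z * plane + (arma::uword)y * nx;
              int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
              for (int xi = x0; xi < x1; ++xi)
                M(row, col0 + xi) = xc[src + xi + dx];
            }
          }
        }
  }
  return M;
}

// Forward 3x3x3 convolution. x: (nx,ny,nz,Cin); W: (Cout, 27*Cin); b: Cout.
// [[Rcpp::export]]
NumericVector conv3d_fw(const NumericVector& x, const arma::mat& W,
                        const arma::vec& b) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("x must be 4D (nx,ny,nz,C)");
  int nx = d[0], ny = d[1], nz = d[2], C = d[3];
  if ((int)W.n_cols != 27 * C) stop("W has wrong inner dimension");
  int Cout = W.n_rows;
  arma::mat M = im2col3(x.begin(), nx, ny, nz, C);
  arma::mat Y = W * M;            // (Cout, N)
  Y.each_col() += b;
  arma::mat Yt = Y.t();           // (N, Cout), column-major == (nx,ny,nz,Cout)
  NumericVector out(Yt.begin(), Yt.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz, Cout);
  return out;
}

// Backward pass; returns gradients wrt input, W and b.
// [[Rcpp::export]]
List conv3d_bw(const NumericVector& x, const arma::mat& W,
               const NumericVector& dy) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], C = d[3];
  int Cout = W.n_rows;
  const arma::uword N = (arma::uword)nx * ny * nz;
  arma::mat dY((double*)dy.begin(), N, Cout);  // (N, Cout) view
  arma::mat M = im2col3(x.begin(), nx, ny, nz, C);
  arma::mat dW = dY.t() * M.t();               // (Cout, 27C)
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dM = W.t() * dY.t();               // (27C, N)

  // col2im scatter-add
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t volsz = plane * nz;
  for (int c = 0; c < C; ++c) {
    double* xc = dx.begin() + (R_xlen_t)c * volsz;
    int koff = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy_ = -1; dy_ <= 1; ++dy_)
        for (int dx_ = -1; dx_ <= 1; ++dx_, ++koff) {
          const arma::uword row = (arma::uword)koff * C + c;
          for (int z = 0; z < nz; ++z) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              int yy = y + dy_;
              if (yy < 0 || yy >= ny) continue;
              R_xlen_t dst = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx;
              arma::uword col0 = (arma::uword)z * plane + (arma::uword)y * nx;
              int x0 = std::max(0, -dx_), x1 = std::min(nx, nx - dx_);
              for (int xi = x0; xi < x1; ++xi)
                xc[dst + xi + dx_] += dM(row, col0 + xi);
            }
          }
        }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling; also returns the argmax linear indices for backward.
// [[Rcpp::export]]
List maxpool3d_fw(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], C = d[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("pooling needs even dimensions");
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  R_xlen_t on = (R_xlen_t)ox * oy * oz * C;
  NumericVector out(on);
  IntegerVector arg(on);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    R_xlen_t cb = (R_xlen_t)c * plane * nz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xi = 0; xi < ox; ++xi, ++o) {
          double best = -INFINITY;
          R_xlen_t bidx = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                R_xlen_t idx = cb + (R_xlen_t)(2 * z + dz) * plane +
                               (R_xlen_t)(2 * y + dy) * nx + (2 * xi + dx);
                if (x[idx] > best) { best = x[idx]; bidx = idx; }
              }
          out[o] = best;
          arg[o] = (int)bidx;
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(const NumericVector& dy, const IntegerVector& argmax,
                           const IntegerVector& in_dim) {
  R_xlen_t n = (R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(n);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  return dx;
}

// Nearest-neighbour x2 upsampling.
// [[Rcpp::export]]
NumericVector upsample2_fw(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], C = d[3];
  int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  NumericVector out((R_xlen_t)ox * oy * oz * C);
  const R_xlen_t iplane = (R_xlen_t)nx * ny, oplane = (R_xlen_t)ox * oy;
  for (int c = 0; c < C; ++c) {
    R_xlen_t ib = (R_xlen_t)c * iplane * nz, ob = (R_xlen_t)c * oplane * oz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y) {
        R_xlen_t irow = ib + (R_xlen_t)(z / 2) * iplane + (R_xlen_t)(y / 2) * nx;
        R_xlen_t orow = ob + (R_xlen_t)z * oplane + (R_xlen_t)y * ox;
        for (int xi = 0; xi < ox; ++xi)
          out[orow + xi] = x[irow + xi / 2];
      }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bw(const NumericVector& dy) {
  IntegerVector d = dy.attr("dim");
  int ox = d[0], oy = d[1], oz = d[2], C = d[3];
  int nx = ox / 2, ny = oy / 2, nz = oz / 2;
  NumericVector dx((R_xlen_t)nx * ny * nz * C);
  const R_xlen_t iplane = (R_xlen_t)nx * ny, oplane = (R_xlen_t)ox * oy;
  for (int c = 0; c < C; ++c) {
    R_xlen_t ib = (R_xlen_t)c * iplane * nz, ob = (R_xlen_t)c * oplane * oz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y) {
        R_xlen_t irow = ib + (R_xlen_t)(z / 2) * iplane + (R_xlen_t)(y / 2) * nx;
        R_xlen_t orow = ob + (R_xlen_t)z * oplane + (R_xlen_t)y * ox;
        for (int xi = 0; xi < ox; ++xi)
          dx[irow + xi / 2] += dy[orow + xi];
      }
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, C);
  return dx;
}
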