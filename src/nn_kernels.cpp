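// Volumetric neural-network kernels and Gaussian rasterization.
//
// Feature maps are (channels x nvox*N) matrices: sample i occupies the
// column block [i*nvox, (i+1)*nvox), voxels in x-fastest (x,y,z) order.
// All spatial grids handled here are cubic (edge^3 voxels), stride-1
// convolutions with TensorFlow-style "same" padding (for even kernels the
// extra padding voxel goes to the trailing side).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int pad_left(int k) { return (k - 1) / 2; }

// Build the transposed im2col matrix (nvox x (c_in*k^3)) for one sample.
// Each column holds one (kernel-offset, channel) pair over all output
// voxels, so the inner loop writes contiguously and copies whole x-rows.
static void im2col3t(const arma::mat& X, int sample, int c_in, int edge,
                     int k, arma::mat& colT) {
  const int nvox = edge * edge * edge;
  const int pl = pad_left(k);
  const arma::uword col0 = (arma::uword)sample * nvox;
  colT.zeros();
  for (int kz = 0; kz < k; ++kz) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int dz = kz - pl, dy = ky - pl, dx = kx - pl;
        // valid output range per axis given the shift
        const int ox0 = std::max(0, -dx), ox1 = std::min(edge, edge - dx);
        const int oy0 = std::max(0, -dy), oy1 = std::min(edge, edge - dy);
        const int oz0 = std::max(0, -dz), oz1 = std::min(edge, edge - dz);
        for (int c = 0; c < c_in; ++c) {
          const int q = c + c_in * (kx + k * (ky + k * kz));
          double* out = colT.colptr(q);
          for (int oz = oz0; oz < oz1; ++oz) {
            const int iz = oz + dz;
            for (int oy = oy0; oy < oy1; ++oy) {
              const int iy = oy + dy;
              const int obase = edge * (oy + edge * oz);
              const arma::uword ibase = col0 + edge * (iy + edge * iz);
              const double* xcol = X.memptr() + (arma::uword)X.n_rows *
                  (ibase + ox0 + dx) + c;
              double* o = out + obase + ox0;
              const int len = ox1 - ox0;
              for (int t = 0; t < len; ++t)
                o[t] = xcol[(arma::uword)t * X.n_rows];
            }
          }
        }
      }
    }
  }
}

// Adjoint: scatter-add colT columns back onto the input grid.
static void col2im3t(const arma::mat& colT, int sample, int c_in, int edge,
                     int k, arma::mat& dX) {
  const int nvox = edge * edge * edge;
  const int pl = pad_left(k);
  const arma::uword col0 = (arma::uword)sample * nvox;
  for (int kz = 0; kz < k; ++kz) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int dz = kz - pl, dy = ky - pl, dx = kx - pl;
        const int ox0 = std::max(0, -dx), ox1 = std::min(edge, edge - dx);
        const int oy0 = std::max(0, -dy), oy1 = std::min(edge, edge - dy);
        const int oz0 = std::max(0, -dz), oz1 = std::min(edge, edge - dz);
        for (int c = 0; c < c_in; ++c) {
          const int q = c + c_in * (kx + k * (ky + k * kz));
          const double* in = colT.colptr(q);
          for (int oz = oz0; oz < oz1; ++oz) {
            const int iz = oz + dz;
            for (int oy = oy0; oy < oy1; ++oy) {
              const int iy = oy + dy;
              const int obase = edge * (oy + edge * oz);
              const arma::uword ibase = col0 + edge * (iy + edge * iz);
              double* xcol = dX.memptr() + (arma::uword)dX.n_rows *
                  (ibase + ox0 + dx) + c;
              const double* o = in + obase + ox0;
              const int len = ox1 - ox0;
              for (int t = 0; t < len; ++t)
                xcol[(arma::uword)t * dX.n_rows] += o[t];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cr_conv3_fwd(const arma::mat& X, const arma::mat& W,
                       const arma::vec& b, int edge, int k, int N) {
  const int c_in = X.n_rows;
  const int nvox = edge * edge * edge;
  const int f = W.n_rows;
  arma::mat Y(f, (arma::uword)nvox * N);
  arma::mat colT(nvox, c_in * k * k * k);
  for (int i = 0; i < N; ++i) {
    im2col3t(X, i, c_in, edge, k, colT);
    Y.cols((arma::uword)i * nvox, (arma::uword)(i + 1) * nvox - 1) =
        W * colT.t();
  }
  Y.each_col() += b;
  return Y;
}

// [[Rcpp::export]]
List cr_conv3_bwd(const arma::mat& X, const arma::mat& W, const arma::mat& dY,
                  int edge, int k, int N) {
  const int c_in = X.n_rows;
  const int nvox = edge * edge * edge;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  arma::vec db = arma::sum(dY, 1);
  arma::mat colT(nvox, c_in * k * k * k);
  for (int i = 0; i < N; ++i) {
    im2col3t(X, i, c_in, edge, k, colT);
    const arma::mat dYi = dY.cols((arma::uword)i * nvox,
                                  (arma::uword)(i + 1) * nvox - 1);
    dW += dYi * colT;
    arma::mat dcolT = dYi.t() * W;   // (nvox x c_in*k^3)
    col2im3t(dcolT, i, c_in, edge, k, dX);
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// 2x2x2 max pooling with stride 2; idx records, per output column/channel,
// the absolute input column index chosen (for the backward pass).
// [[Rcpp::export]]
List cr_maxpool_fwd(const arma::mat& X, int edge, int N) {
  const int c = X.n_rows;
  const int eo = edge / 2;
  const int nvo = eo * eo * eo;
  const int nvi = edge * edge * edge;
  arma::mat Y(c, (arma::uword)nvo * N);
  arma::umat idx(c, (arma::uword)nvo * N);
  for (int i = 0; i < N; ++i) {
    for (int oz = 0; oz < eo; ++oz)
      for (int oy = 0; oy < eo; ++oy)
        for (int ox = 0; ox < eo; ++ox) {
          const arma::uword ocol =
              (arma::uword)i * nvo + ox + eo * (oy + eo * oz);
          for (int ch = 0; ch < c; ++ch) {
            double best = -arma::datum::inf;
            arma::uword bestcol = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const arma::uword icol = (arma::uword)i * nvi +
                      (2 * ox + dx) + edge * ((2 * oy + dy) +
                                              edge * (2 * oz + dz));
                  const double v = X(ch, icol);
                  if (v > best) { best = v; bestcol = icol; }
                }
            Y(ch, ocol) = best;
            idx(ch, ocol) = bestcol;
          }
        }
  }
  return List::create(Named("Y") = Y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat cr_maxpool_bwd(const arma::mat& dY, const arma::umat& idx,
                         int nvox_in, int N) {
  const int c = dY.n_rows;
  arma::mat dX(c, (arma::uword)nvox_in * N, arma::fill::zeros);
  for (arma::uword j = 0; j < dY.n_cols; ++j)
    for (int ch = 0; ch < c; ++ch)
      dX(ch, idx(ch, j)) += dY(ch, j);
  return dX;
}

// Nearest-neighbour x2 upsampling.
// [[Rcpp::export]]
arma::mat cr_upsample_fwd(const arma::mat& X, int edge, int N) {
  const int c = X.n_rows;
  const int eo = edge * 2;
  const int nvi = edge * edge * edge;
  const int nvo = eo * eo * eo;
  arma::mat Y(c, (arma::uword)nvo * N);
  for (int i = 0; i < N; ++i)
    for (int oz = 0; oz < eo; ++oz)
      for (int oy = 0; oy < eo; ++oy)
        for (int ox = 0; ox < eo; ++ox) {
          const arma::uword ocol =
              (arma::uword)i * nvo + ox + eo * (oy + eo * oz);
          const arma::uword icol = (arma::uword)i * nvi +
              (ox / 2) + edge * ((oy / 2) + edge * (oz / 2));
          Y.col(ocol) = X.col(icol);
        }
  return Y;
}

// [[Rcpp::export]]
arma::mat cr_upsample_bwd(const arma::mat& dY, int edge_out, int N) {
  const int c = dY.n_rows;
  const int ei = edge_out / 2;
  const int nvi = ei * ei * ei;
  const int nvo = edge_out * edge_out * edge_out;
  arma::mat dX(c, (arma::uword)nvi * N, arma::fill::zeros);
  for (int i = 0; i < N; ++i)
    for (int oz = 0; oz < edge_out; ++oz)
      for (int oy = 0; oy < edge_out; ++oy)
        for (int ox = 0; ox < edge_out; ++ox) {
          const arma::uword ocol =
              (arma::uword)i * nvo + ox + edge_out * (oy + edge_out * oz);
          const arma::uword icol = (arma::uword)i * nvi +
              (ox / 2) + ei * ((oy / 2) + ei * (oz / 2));
          dX.col(icol) += dY.col(ocol);
        }
  return dX;
}

static inline int wrap_idx(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// Rasterize atoms as mass-normalized 3D Gaussians, truncated at
// `cutoff` (Angstrom). Positions in Angstrom relative to the grid origin;
// voxel centres sit at (i + 0.5) * voxel. With wrap = true the Gaussian
// wraps circularly at the box boundary (periodic/DFT semantics).
// [[Rcpp::export]]
NumericVector cr_rasterize_gauss(const arma::mat& pos, const arma::vec& w,
                                 IntegerVector box, NumericVector voxel,
                                 double sigma, double cutoff,
                                 bool wrap = false) {
  const int nx = box[0], ny = box[1], nz = box[2];
  const double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  NumericVector out(Dimension(nx, ny, nz));
  double* o = out.begin();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) *
                             sigma * sigma * sigma);
  const double c2 = cutoff * cutoff;
  for (arma::uword a = 0; a < pos.n_rows; ++a) {
    const double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    const double amp = w(a) * norm;
    int x0 = (int)std::floor((px - cutoff) / vx - 0.5);
    int x1 = (int)std::ceil((px + cutoff) / vx - 0.5);
    int y0 = (int)std::floor((py - cutoff) / vy - 0.5);
    int y1 = (int)std::ceil((py + cutoff) / vy - 0.5);
    int z0 = (int)std::floor((pz - cutoff) / vz - 0.5);
    int z1 = (int)std::ceil((pz + cutoff) / vz - 0.5);
    if (!wrap) {
      x0 = std::max(0, x0); x1 = std::min(nx - 1, x1);
      y0 = std::max(0, y0); y1 = std::min(ny - 1, y1);
      z0 = std::max(0, z0); z1 = std::min(nz - 1, z1);
    }
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = (iz + 0.5) * vz - pz;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = (iy + 0.5) * vy - py;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > c2) continue;
        double* plane = o + (arma::uword)nx *
            (wrap_idx(iy, ny) + (arma::uword)ny * wrap_idx(iz, nz));
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = (ix + 0.5) * vx - px;
          const double r2 = dx * dx + dyz2;
          if (r2 <= c2)
            plane[wrap_idx(ix, nx)] += amp * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// Logical mask of voxels within `radius` (Angstrom, true non-periodic
// distance) of any atom.
// [[Rcpp::export]]
LogicalVector cr_support_mask(const arma::mat& pos, IntegerVector box,
                              NumericVector voxel, double radius) {
  const int nx = box[0], ny = box[1], nz = box[2];
  const double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  LogicalVector out(Dimension(nx, ny, nz));
  int* o = out.begin();
  const double r2max = radius * radius;
  for (arma::uword a = 0; a < pos.n_rows; ++a) {
    const double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    const int x0 = std::max(0, (int)std::floor((px - radius) / vx - 0.5));
    const int x1 = std::min(nx - 1, (int)std::ceil((px + radius) / vx - 0.5));
    const int y0 = std::max(0, (int)std::floor((py - radius) / vy - 0.5));
    const int y1 = std::min(ny - 1, (int)std::ceil((py + radius) / vy - 0.5));
    const int z0 = std::max(0, (int)std::floor((pz - radius) / vz - 0.5));
    const int z1 = std::min(nz - 1, (int)std::ceil((pz + radius) / vz - 0.5));
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = (iz + 0.5) * vz - pz;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = (iy + 0.5) * vy - py;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2max) continue;
        int* plane = o + (arma::uword)nx * (iy + (arma::uword)ny * iz);
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = (ix + 0.5) * vx - px;
          if (dx * dx + dyz2 <= r2max) plane[ix] = 1;
        }
      }
    }
  }
  return out;
}
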