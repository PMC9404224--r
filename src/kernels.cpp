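// Low-level numerical kernels: 3D convolution (im2col + GEMM), strided
// transposed convolution, connected-component labelling, resampling/warping,
// marching-tetrahedra volume, and brute-force pairwise distances.
// Feature maps are (channels x voxels) matrices; voxel linear index is
// x + nx*(y + ny*z), matching R's column-major array order.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::mat;
using arma::vec;

// Convolution arithmetic runs in single precision (the conventional CNN
// precision) on reusable buffers; the R interface stays double.

static std::vector<float> g_buf_cols;   // im2col arena, grown on demand
static std::vector<float> g_buf_a, g_buf_b, g_buf_c;  // padded-grid arenas

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

static inline int out_len(int n, int stride) {
  // kernel 3, pad 1
  return (n - 1) / stride + 1;
}

static fmat to_f(const NumericMatrix& x) {
  fmat out(x.nrow(), x.ncol());
  const double* src = x.begin();
  float* dst = out.memptr();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static NumericMatrix to_d(const fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  const float* src = x.memptr();
  double* dst = out.begin();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

// Fill the im2col buffer for a 3x3x3 kernel with pad 1.
// cols: (Cin*27) x (ox*oy*oz); row order = offset-major, channel-fastest,
// offsets ordered kx fastest, then ky, then kz.
static void im2col3(const fmat& X, int nx, int ny, int nz, int stride,
                    fmat& cols, int ox, int oy, int oz) {
  const int Cin = X.n_rows;
  long col = 0;
  for (int z = 0; z < oz; ++z) {
    for (int y = 0; y < oy; ++y) {
      for (int x = 0; x < ox; ++x) {
        const int bx = x * stride - 1, by = y * stride - 1, bz = z * stride - 1;
        float* cp = cols.colptr(col);
        int r = 0;
        for (int kz = 0; kz < 3; ++kz) {
          const int iz = bz + kz;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = by + ky;
            for (int kx = 0; kx < 3; ++kx) {
              const int ix = bx + kx;
              if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
                const float* xp = X.colptr(ix + nx * (iy + (long)ny * iz));
                std::copy(xp, xp + Cin, cp + r);
              } else {
                std::fill(cp + r, cp + r + Cin, 0.0f);
              }
              r += Cin;
            }
          }
        }
        ++col;
      }
    }
  }
}

static fmat arena_mat(std::vector<float>& arena, size_t rows, size_t cols) {
  if (arena.size() < rows * cols) arena.resize(rows * cols);
  return fmat(arena.data(), rows, cols, false, true);
}

// [[Rcpp::export]]
List conv3_fwd_cpp(NumericMatrix X, IntegerVector dims, NumericMatrix W,
                   NumericVector b, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_len(nx, stride), oy = out_len(ny, stride), oz = out_len(nz, stride);
  const long N = (long)ox * oy * oz;
  const fmat Xf = to_f(X), Wf = to_f(W);
  fmat cols = arena_mat(g_buf_cols, (size_t)Xf.n_rows * 27, N);
  im2col3(Xf, nx, ny, nz, stride, cols, ox, oy, oz);
  fmat Y = Wf * cols;
  fvec bf(b.size());
  for (int i = 0; i < b.size(); ++i) bf[i] = (float)b[i];
  Y.each_col() += bf;
  return List::create(_["Y"] = to_d(Y),
                      _["odim"] = IntegerVector::create(ox, oy, oz));
}

// [[Rcpp::export]]
List conv3_bwd_cpp(NumericMatrix X, IntegerVector dims, NumericMatrix W,
                   int stride, NumericMatrix dY) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_len(nx, stride), oy = out_len(ny, stride), oz = out_len(nz, stride);
  const fmat Xf = to_f(X), Wf = to_f(W), dYf = to_f(dY);
  const int Cin = Xf.n_rows;
  const long N = (long)ox * oy * oz;
  fmat cols = arena_mat(g_buf_cols, (size_t)Cin * 27, N);
  im2col3(Xf, nx, ny, nz, stride, cols, ox, oy, oz);
  fmat dW = dYf * cols.t();
  fvec db = arma::sum(dYf, 1);
  // reuse the arena for dcols (cols no longer needed)
  fmat dcols = Wf.t() * dYf;  // (Cin*27) x N
  fmat dX(Cin, Xf.n_cols, arma::fill::zeros);
  // col2im: scatter-add
  long col = 0;
  for (int z = 0; z < oz; ++z) {
    for (int y = 0; y < oy; ++y) {
      for (int x = 0; x < ox; ++x) {
        const int bx = x * stride - 1, by = y * stride - 1, bz = z * stride - 1;
        const float* cp = dcols.colptr(col);
        int r = 0;
        for (int kz = 0; kz < 3; ++kz) {
          const int iz = bz + kz;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = by + ky;
            for (int kx = 0; kx < 3; ++kx) {
              const int ix = bx + kx;
              if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
                float* xp = dX.colptr(ix + nx * (iy + (long)ny * iz));
                for (int c = 0; c < Cin; ++c) xp[c] += cp[r + c];
              }
              r += Cin;
            }
          }
        }
        ++col;
      }
    }
  }
  NumericVector dbv(db.n_elem);
  for (size_t i = 0; i < db.n_elem; ++i) dbv[i] = db[i];
  return List::create(_["dW"] = to_d(dW), _["db"] = dbv, _["dX"] = to_d(dX));
}

// ---- stride-1 convolution via shift-and-GEMM on a zero-padded grid ---------
// For stride 1 the im2col buffer is 27x the feature map; instead we copy the
// map once into a one-voxel zero-padded grid and run one GEMM per kernel
// offset directly on pointer-shifted column ranges (beta = 1 accumulation).

// Copy a C x (nx*ny*nz) map into a C x ((nx+2)(ny+2)(nz+2)) padded grid.
static void pad_grid(const fmat& X, int nx, int ny, int nz, fmat& P) {
  const int C = X.n_rows;
  const int px = nx + 2, py = ny + 2;
  P.zeros();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const float* src = X.colptr((long)nx * (y + (long)ny * z));
      float* dst = P.colptr(1 + (long)px * ((y + 1) + (long)py * (z + 1)));
      std::copy(src, src + (size_t)C * nx, dst);
    }
}

static void unpad_grid(const fmat& P, int nx, int ny, int nz, fmat& X) {
  const int C = P.n_rows;
  const int px = nx + 2, py = ny + 2;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const float* src = P.colptr(1 + (long)px * ((y + 1) + (long)py * (z + 1)));
      float* dst = X.colptr((long)nx * (y + (long)ny * z));
      std::copy(src, src + (size_t)C * nx, dst);
    }
}

// [[Rcpp::export]]
List conv3s1_fwd_cpp(NumericMatrix X, IntegerVector dims, NumericMatrix W,
                     NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const fmat Xf = to_f(X), Wf = to_f(W);
  const int Cin = Xf.n_rows, Cout = Wf.n_rows;
  const long P = (long)(nx + 2) * (ny + 2) * (nz + 2);
  fmat Xpad = arena_mat(g_buf_a, Cin, P);
  pad_grid(Xf, nx, ny, nz, Xpad);
  fmat Ypad = arena_mat(g_buf_b, Cout, P);
  Ypad.zeros();
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int o = kx + 3 * (ky + 3 * kz);
        const long d = (kx - 1) + (long)(nx + 2) * ((ky - 1) + (long)(ny + 2) * (kz - 1));
        const long lo = d < 0 ? -d : 0, hi = P - 1 - (d > 0 ? d : 0);
        const int len = (int)(hi - lo + 1);
        sgemm('N', 'N', Cout, len, Cin, 1.0f,
              Wf.colptr((size_t)o * Cin), Cout,
              Xpad.colptr(lo + d), Cin,
              1.0f, Ypad.colptr(lo), Cout);
      }
  fmat Y(Cout, (long)nx * ny * nz);
  unpad_grid(Ypad, nx, ny, nz, Y);
  fvec bf(b.size());
  for (int i = 0; i < b.size(); ++i) bf[i] = (float)b[i];
  Y.each_col() += bf;
  return List::create(_["Y"] = to_d(Y),
                      _["odim"] = IntegerVector::create(nx, ny, nz));
}

// [[Rcpp::export]]
List conv3s1_bwd_cpp(NumericMatrix X, IntegerVector dims, NumericMatrix W,
                     NumericMatrix dY) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const fmat Xf = to_f(X), Wf = to_f(W), dYf = to_f(dY);
  const int Cin = Xf.n_rows, Cout = Wf.n_rows;
  const long P = (long)(nx + 2) * (ny + 2) * (nz + 2);
  fmat Xpad = arena_mat(g_buf_a, Cin, P);
  pad_grid(Xf, nx, ny, nz, Xpad);
  fmat dYpad = arena_mat(g_buf_b, Cout, P);
  pad_grid(dYf, nx, ny, nz, dYpad);
  fmat dXpad = arena_mat(g_buf_c, Cin, P);
  dXpad.zeros();
  fmat dW(Cout, (size_t)Cin * 27);
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int o = kx + 3 * (ky + 3 * kz);
        const long d = (kx - 1) + (long)(nx + 2) * ((ky - 1) + (long)(ny + 2) * (kz - 1));
        const long lo = d < 0 ? -d : 0, hi = P - 1 - (d > 0 ? d : 0);
        const int len = (int)(hi - lo + 1);
        // dW_o = dY * X_shifted^T  (padding columns of dY are zero)
        sgemm('N', 'T', Cout, Cin, len, 1.0f,
              dYpad.colptr(lo), Cout,
              Xpad.colptr(lo + d), Cin,
              0.0f, dW.colptr((size_t)o * Cin), Cout);
        // dX_shifted += W_o^T * dY
        sgemm('T', 'N', Cin, len, Cout, 1.0f,
              Wf.colptr((size_t)o * Cin), Cout,
              dYpad.colptr(lo), Cout,
              1.0f, dXpad.colptr(lo + d), Cin);
      }
  fmat dX(Cin, (long)nx * ny * nz);
  unpad_grid(dXpad, nx, ny, nz, dX);
  fvec db = arma::sum(dYf, 1);
  NumericVector dbv(db.n_elem);
  for (size_t i = 0; i < db.n_elem; ++i) dbv[i] = db[i];
  return List::create(_["dW"] = to_d(dW), _["db"] = dbv, _["dX"] = to_d(dX));
}

// Transposed convolution, kernel 2, stride 2 (doubles each spatial dim).
// W: Cout x (Cin*8), offset-major blocks, offsets ordered ox fastest.
// [[Rcpp::export]]
List upconv2_fwd_cpp(NumericMatrix X, IntegerVector dims, NumericMatrix W,
                     NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const fmat Xf = to_f(X), Wf = to_f(W);
  const int Cin = Xf.n_rows, Cout = Wf.n_rows;
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  fmat Y(Cout, (long)mx * my * mz);
  fvec bf(b.size());
  for (int i = 0; i < b.size(); ++i) bf[i] = (float)b[i];
  Y.each_col() = bf;
  for (int o = 0; o < 8; ++o) {
    const int ax = o & 1, ay = (o >> 1) & 1, az = (o >> 2) & 1;
    fmat Yo = Wf.cols((size_t)o * Cin, (size_t)(o + 1) * Cin - 1) * Xf;  // Cout x Nin
    long i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const long j = (2 * x + ax) + (long)mx * ((2 * y + ay) + (long)my * (2 * z + az));
          float* yp = Y.colptr(j);
          const float* sp = Yo.colptr(i++);
          for (int c = 0; c < Cout; ++c) yp[c] += sp[c];
        }
  }
  return List::create(_["Y"] = to_d(Y),
                      _["odim"] = IntegerVector::create(mx, my, mz));
}

// [[Rcpp::export]]
List upconv2_bwd_cpp(NumericMatrix X, IntegerVector dims, NumericMatrix W,
                     NumericMatrix dY) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const fmat Xf = to_f(X), Wf = to_f(W), dYf = to_f(dY);
  const int Cin = Xf.n_rows, Cout = Wf.n_rows;
  const int mx = 2 * nx, my = 2 * ny;
  fmat dW(Cout, (size_t)Cin * 8);
  fmat dX(Cin, Xf.n_cols, arma::fill::zeros);
  fvec db = arma::sum(dYf, 1);
  fmat dYo(Cout, Xf.n_cols);
  for (int o = 0; o < 8; ++o) {
    const int ax = o & 1, ay = (o >> 1) & 1, az = (o >> 2) & 1;
    long i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const long j = (2 * x + ax) + (long)mx * ((2 * y + ay) + (long)my * (2 * z + az));
          dYo.col(i++) = dYf.col(j);
        }
    dW.cols((size_t)o * Cin, (size_t)(o + 1) * Cin - 1) = dYo * Xf.t();
    dX += Wf.cols((size_t)o * Cin, (size_t)(o + 1) * Cin - 1).t() * dYo;
  }
  NumericVector dbv(db.n_elem);
  for (size_t i = 0; i < db.n_elem; ++i) dbv[i] = db[i];
  return List::create(_["dW"] = to_d(dW), _["db"] = dbv, _["dX"] = to_d(dX));
}

// Instance normalization over voxels, per channel, with optional fused
// ReLU. Double precision throughout (cheap relative to the convolutions).
// [[Rcpp::export]]
List in_fwd_cpp(NumericMatrix X, NumericVector g, NumericVector b,
                double eps, bool relu) {
  const int C = X.nrow();
  const long N = X.ncol();
  std::vector<double> s(C, 0.0), s2(C, 0.0);
  const double* x = X.begin();
  for (long j = 0; j < N; ++j) {
    const double* col = x + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      s[c] += col[c];
      s2[c] += col[c] * col[c];
    }
  }
  NumericVector istd(C);
  std::vector<double> mu(C);
  for (int c = 0; c < C; ++c) {
    mu[c] = s[c] / N;
    const double v = s2[c] / N - mu[c] * mu[c];
    istd[c] = 1.0 / std::sqrt((v > 0 ? v : 0) + eps);
  }
  NumericMatrix Y(C, N), Xhat(C, N);
  double* y = Y.begin();
  double* xh = Xhat.begin();
  for (long j = 0; j < N; ++j) {
    const double* col = x + (size_t)j * C;
    double* yc = y + (size_t)j * C;
    double* hc = xh + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      const double h = (col[c] - mu[c]) * istd[c];
      hc[c] = h;
      double v = h * g[c] + b[c];
      if (relu && v < 0) v = 0;
      yc[c] = v;
    }
  }
  return List::create(_["y"] = Y, _["xhat"] = Xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List in_bwd_cpp(NumericMatrix dY, NumericMatrix Xhat, NumericVector istd,
                NumericVector g) {
  const int C = dY.nrow();
  const long N = dY.ncol();
  std::vector<double> m1(C, 0.0), m2(C, 0.0);
  NumericVector dg(C), db(C);
  const double* dy = dY.begin();
  const double* xh = Xhat.begin();
  for (long j = 0; j < N; ++j) {
    const double* dc = dy + (size_t)j * C;
    const double* hc = xh + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      const double dxh = dc[c] * g[c];
      m1[c] += dxh;
      m2[c] += dxh * hc[c];
      dg[c] += dc[c] * hc[c];
      db[c] += dc[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    m1[c] /= N;
    m2[c] /= N;
  }
  NumericMatrix dX(C, N);
  double* dx = dX.begin();
  for (long j = 0; j < N; ++j) {
    const double* dc = dy + (size_t)j * C;
    const double* hc = xh + (size_t)j * C;
    double* oc = dx + (size_t)j * C;
    for (int c = 0; c < C; ++c)
      oc[c] = istd[c] * (dc[c] * g[c] - m1[c] - hc[c] * m2[c]);
  }
  return List::create(_["dx"] = dX, _["dg"] = dg, _["db"] = db);
}

// Connected-component labelling of a binary 3D array.
// connectivity: 6 or 26. Components are numbered 1..K in order of their
// seed voxel (smallest linear index), background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  // neighbour offsets
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / ((long)nx * ny);
      for (const auto& d : nb) {
        const int X2 = x + d[0], Y2 = y + d[1], Z2 = z + d[2];
        if (X2 < 0 || X2 >= nx || Y2 < 0 || Y2 >= ny || Z2 < 0 || Z2 >= nz) continue;
        const long w = X2 + nx * (Y2 + (long)ny * Z2);
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// [[Rcpp::export]]
double max_pairwise_dist_cpp(const arma::mat& coords) {
  const long n = coords.n_rows;
  double best = 0.0;
  for (long i = 0; i + 1 < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (long j = i + 1; j < n; ++j) {
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi, dz = coords(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Indices (1-based) of foreground voxels with at least one 6-neighbour
// outside the mask (or outside the grid).
// [[Rcpp::export]]
IntegerVector surface_voxels_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> out;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const long v = x + nx * (y + (long)ny * z);
        if (mask[v] == 0) continue;
        bool surf = false;
        for (int k = 0; k < 6 && !surf; ++k) {
          const int X2 = x + dx[k], Y2 = y + dy[k], Z2 = z + dz[k];
          if (X2 < 0 || X2 >= nx || Y2 < 0 || Y2 >= ny || Z2 < 0 || Z2 >= nz ||
              mask[X2 + nx * (Y2 + (long)ny * Z2)] == 0)
            surf = true;
        }
        if (surf) out.push_back(v + 1);
      }
  return wrap(out);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Resample a 3D scalar array onto a new grid. Voxel centre of output index i
// maps to input continuous index i * out_spacing / in_spacing (shared origin
// at the centre of voxel 0). nearest = TRUE for label images.
// [[Rcpp::export]]
NumericVector resample3_cpp(NumericVector x, IntegerVector dims,
                            NumericVector in_spacing, IntegerVector odims,
                            NumericVector out_spacing, bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  const double rx = out_spacing[0] / in_spacing[0];
  const double ry = out_spacing[1] / in_spacing[1];
  const double rz = out_spacing[2] / in_spacing[2];
  NumericVector out((long)ox * oy * oz);
  long o = 0;
  for (int z = 0; z < oz; ++z) {
    const double fz = clampd(z * rz, 0, nz - 1);
    for (int y = 0; y < oy; ++y) {
      const double fy = clampd(y * ry, 0, ny - 1);
      for (int xo = 0; xo < ox; ++xo) {
        const double fx = clampd(xo * rx, 0, nx - 1);
        if (nearest) {
          const int ix = (int)std::lround(fx), iy = (int)std::lround(fy), iz = (int)std::lround(fz);
          out[o++] = x[ix + nx * (iy + (long)ny * iz)];
        } else {
          const int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
          const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                    z1 = std::min(z0 + 1, nz - 1);
          const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          double acc = 0.0;
          for (int cz = 0; cz <= 1; ++cz)
            for (int cy = 0; cy <= 1; ++cy)
              for (int cx = 0; cx <= 1; ++cx) {
                const double w = (cx ? tx : 1 - tx) * (cy ? ty : 1 - ty) * (cz ? tz : 1 - tz);
                if (w == 0.0) continue;
                acc += w * x[(cx ? x1 : x0) + nx * ((cy ? y1 : y0) + (long)ny * (cz ? z1 : z0))];
              }
          out[o++] = acc;
        }
      }
    }
  }
  return out;
}

// Backward warp: sample x at (i + displacement[i]) (displacements in voxels).
// [[Rcpp::export]]
NumericVector warp3_cpp(NumericVector x, IntegerVector dims,
                        NumericVector dxf, NumericVector dyf, NumericVector dzf,
                        bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  NumericVector out(n);
  long v = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xo = 0; xo < nx; ++xo) {
        const double fx = clampd(xo + dxf[v], 0, nx - 1);
        const double fy = clampd(y + dyf[v], 0, ny - 1);
        const double fz = clampd(z + dzf[v], 0, nz - 1);
        if (nearest) {
          out[v] = x[(int)std::lround(fx) + nx * ((int)std::lround(fy) + (long)ny * (int)std::lround(fz))];
        } else {
          const int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
          const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                    z1 = std::min(z0 + 1, nz - 1);
          const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          double acc = 0.0;
          for (int cz = 0; cz <= 1; ++cz)
            for (int cy = 0; cy <= 1; ++cy)
              for (int cx = 0; cx <= 1; ++cx) {
                const double w = (cx ? tx : 1 - tx) * (cy ? ty : 1 - ty) * (cz ? tz : 1 - tz);
                if (w == 0.0) continue;
                acc += w * x[(cx ? x1 : x0) + nx * ((cy ? y1 : y0) + (long)ny * (cz ? z1 : z0))];
              }
          out[v] = acc;
        }
        ++v;
      }
  return out;
}

// Volume enclosed by the linear-interpolation iso-surface of a binary mask.
// The grid of voxel centres (padded by one background layer) is split into
// cells, each cell into six tetrahedra sharing the main diagonal; within a
// tetrahedron the field is linear, so the sub-volume above `level` has a
// closed form. Equivalent to the volume bounded by a marching-tetrahedra
// mesh extracted at `level`.
static double tet_clip_volume(const double p[4][3], const double v[4], double level) {
  // signed volume of the tetra
  double a[3], b[3], c[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = p[1][k] - p[0][k];
    b[k] = p[2][k] - p[0][k];
    c[k] = p[3][k] - p[0][k];
  }
  const double det = a[0] * (b[1] * c[2] - b[2] * c[1]) -
                     a[1] * (b[0] * c[2] - b[2] * c[0]) +
                     a[2] * (b[0] * c[1] - b[1] * c[0]);
  const double V = std::fabs(det) / 6.0;
  int in[4], nin = 0;
  for (int i = 0; i < 4; ++i) {
    in[i] = v[i] > level;
    nin += in[i];
  }
  if (nin == 0) return 0.0;
  if (nin == 4) return V;
  auto frac = [&](int i, int j) {  // edge fraction from vertex i towards j where f = level
    return (v[i] - level) / (v[i] - v[j]);
  };
  if (nin == 1) {
    int i = 0;
    while (!in[i]) ++i;
    double prod = 1.0;
    for (int j = 0; j < 4; ++j)
      if (j != i) prod *= frac(i, j);
    return V * prod;
  }
  if (nin == 3) {
    int i = 0;
    while (in[i]) ++i;
    double prod = 1.0;
    for (int j = 0; j < 4; ++j)
      if (j != i) prod *= frac(i, j);
    return V * (1.0 - prod);
  }
  // nin == 2: convex wedge; cone from inside vertex A over the faces not
  // containing it. Vertices: A, B inside; C, D outside.
  int A = -1, B = -1, C = -1, D = -1;
  for (int i = 0; i < 4; ++i) {
    if (in[i]) { if (A < 0) A = i; else B = i; }
    else       { if (C < 0) C = i; else D = i; }
  }
  double PAC[3], PAD[3], PBC[3], PBD[3];
  const double tAC = frac(A, C), tAD = frac(A, D), tBC = frac(B, C), tBD = frac(B, D);
  for (int k = 0; k < 3; ++k) {
    PAC[k] = p[A][k] + tAC * (p[C][k] - p[A][k]);
    PAD[k] = p[A][k] + tAD * (p[D][k] - p[A][k]);
    PBC[k] = p[B][k] + tBC * (p[C][k] - p[B][k]);
    PBD[k] = p[B][k] + tBD * (p[D][k] - p[B][k]);
  }
  auto tetv = [](const double* q0, const double* q1, const double* q2, const double* q3) {
    double a[3], b[3], c[3];
    for (int k = 0; k < 3; ++k) {
      a[k] = q1[k] - q0[k];
      b[k] = q2[k] - q0[k];
      c[k] = q3[k] - q0[k];
    }
    const double det = a[0] * (b[1] * c[2] - b[2] * c[1]) -
                       a[1] * (b[0] * c[2] - b[2] * c[0]) +
                       a[2] * (b[0] * c[1] - b[1] * c[0]);
    return std::fabs(det) / 6.0;
  };
  return tetv(p[A], p[B], PBC, PBD) + tetv(p[A], PAC, PBC, PBD) + tetv(p[A], PAC, PBD, PAD);
}

// [[Rcpp::export]]
double tetra_mesh_volume_cpp(IntegerVector mask, IntegerVector dims,
                             NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // padded grid of nx+2 etc. voxel centres; cells between consecutive centres
  auto val = [&](int x, int y, int z) -> double {
    // coordinates in the padded grid; map back to mask indices
    const int ix = x - 1, iy = y - 1, iz = z - 1;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) return 0.0;
    return (double)mask[ix + nx * (iy + (long)ny * iz)];
  };
  // Kuhn split: six tetrahedra per cell, all containing the main diagonal
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  double total = 0.0;
  const double cellvol = sx * sy * sz;
  for (int z = 0; z + 1 < nz + 2; ++z)
    for (int y = 0; y + 1 < ny + 2; ++y)
      for (int x = 0; x + 1 < nx + 2; ++x) {
        double vals[8];
        int sum = 0;
        for (int o = 0; o < 8; ++o) {
          vals[o] = val(x + (o & 1), y + ((o >> 1) & 1), z + ((o >> 2) & 1));
          sum += (int)vals[o];
        }
        if (sum == 0) continue;
        if (sum == 8) {
          total += cellvol;
          continue;
        }
        for (int t = 0; t < 6; ++t) {
          // vertices along the permutation path 0 -> e_p0 -> e_p0+e_p1 -> (1,1,1)
          int corner[4] = {0, 0, 0, 7};
          corner[1] = 1 << perms[t][0];
          corner[2] = (1 << perms[t][0]) | (1 << perms[t][1]);
          double p[4][3], v[4];
          for (int i = 0; i < 4; ++i) {
            const int o = corner[i];
            p[i][0] = (x + (o & 1)) * sx;
            p[i][1] = (y + ((o >> 1) & 1)) * sy;
            p[i][2] = (z + ((o >> 2) & 1)) * sz;
            v[i] = vals[o];
          }
          total += tet_clip_volume(p, v, level);
        }
      }
  return total;
}
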