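// Low-level 3D convolution kernels for the encoder-decoder network.
//
// Feature maps are dense numeric arrays with dim (d1, d2, d3, C) in R's
// column-major order, so each channel is a contiguous block of N = d1*d2*d3
// doubles and the array is memory-identical to an (N x C) matrix.  All
// convolutions are expressed as im2col / col2im plus one GEMM, which keeps
// the heavy lifting inside BLAS.
//
// Three layer geometries are needed:
//   * conv3:  kernel 3, stride 1, zero pad 1 (same-size convolution)
//   * down2:  kernel 2, stride 2, no pad (halving; patches do not overlap)
//   * up2:    transposed kernel-2 stride-2 convolution (doubling)
//
// Weight layouts (frozen; the R side initialises to match):
//   conv3:  W is (27*ci x co), patch column index = c*27 + (kz*9 + ky*3 + kx)
//           with offsets kx,ky,kz in {0,1,2} meaning spatial shift -1,0,+1.
//   down2:  W is (8*ci x co),  column index = c*8 + (az*4 + ay*2 + ax)
//   up2:    W is (ci x 8*co),  column index = c*8 + (az*4 + ay*2 + ax)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat as_mat_view(const NumericVector& x, int N, int C) {
  return arma::mat(const_cast<double*>(x.begin()), N, C, false, true);
}

// ---- conv3 (k3 s1 p1) -------------------------------------------------

static void im2col_k3_into(const double* x, double* Pbuf,
                           int d1, int d2, int d3, int ci) {
  const int N = d1 * d2 * d3;
  std::fill(Pbuf, Pbuf + (size_t)N * 27 * ci, 0.0);
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + (size_t)c * N;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          double* col = Pbuf + (size_t)N * (c * 27 + kz * 9 + ky * 3 + kx);
          const int ox = kx - 1, oy = ky - 1, oz = kz - 1;
          for (int z = 0; z < d3; ++z) {
            const int sz = z + oz;
            if (sz < 0 || sz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int sy = y + oy;
              if (sy < 0 || sy >= d2) continue;
              const int x0 = std::max(0, -ox), x1 = std::min(d1, d1 - ox);
              double* dst = col + (size_t)(z * d2 + y) * d1;
              const double* src = xc + (size_t)(sz * d2 + sy) * d1 + ox;
              for (int xx = x0; xx < x1; ++xx) dst[xx] = src[xx];
            }
          }
        }
  }
}

static arma::mat im2col_k3(const double* x, int d1, int d2, int d3, int ci) {
  const int N = d1 * d2 * d3;
  arma::mat P(N, 27 * ci);
  im2col_k3_into(x, P.memptr(), d1, d2, d3, ci);
  return P;
}

static void col2im_k3(const arma::mat& Pg, double* dx,
                      int d1, int d2, int d3, int ci) {
  const int N = d1 * d2 * d3;
  std::fill(dx, dx + (size_t)N * ci, 0.0);
  for (int c = 0; c < ci; ++c) {
    double* xc = dx + (size_t)c * N;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          const double* col = Pg.colptr(c * 27 + kz * 9 + ky * 3 + kx);
          const int ox = kx - 1, oy = ky - 1, oz = kz - 1;
          for (int z = 0; z < d3; ++z) {
            const int sz = z + oz;
            if (sz < 0 || sz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int sy = y + oy;
              if (sy < 0 || sy >= d2) continue;
              const int x0 = std::max(0, -ox), x1 = std::min(d1, d1 - ox);
              const double* src = col + (size_t)(z * d2 + y) * d1;
              double* dst = xc + (size_t)(sz * d2 + sy) * d1 + ox;
              for (int xx = x0; xx < x1; ++xx) dst[xx] += src[xx];
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix w, NumericVector b) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ci = dims[3];
  const int N = d1 * d2 * d3, co = w.ncol();
  arma::mat P = im2col_k3(x.begin(), d1, d2, d3, ci);
  arma::mat W = as_mat_view(NumericVector(w), 27 * ci, co);
  NumericVector y((size_t)N * co);
  arma::mat Y(y.begin(), N, co, false, true);
  Y = P * W;
  for (int c = 0; c < co; ++c) Y.col(c) += b[c];
  y.attr("dim") = IntegerVector::create(d1, d2, d3, co);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector dims,
                   NumericMatrix w, NumericVector dy, bool need_dx = true) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ci = dims[3];
  const int N = d1 * d2 * d3, co = w.ncol();
  arma::mat P = im2col_k3(x.begin(), d1, d2, d3, ci);
  arma::mat W = as_mat_view(NumericVector(w), 27 * ci, co);
  arma::mat dY = as_mat_view(dy, N, co);
  NumericMatrix dw(27 * ci, co);
  arma::mat dWv(dw.begin(), 27 * ci, co, false, true);
  dWv = P.t() * dY;
  NumericVector db(co);
  for (int c = 0; c < co; ++c) db[c] = arma::accu(dY.col(c));
  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dw"] = dw, _["db"] = db);
  arma::mat Pg = dY * W.t();
  NumericVector dx((size_t)N * ci);
  col2im_k3(Pg, dx.begin(), d1, d2, d3, ci);
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, ci);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- elementwise / normalization helpers ------------------------------

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const size_t n = y.size();
  for (size_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector xpre) {
  NumericVector dx = clone(dy);
  double* p = dx.begin();
  const double* q = xpre.begin();
  const size_t n = dx.size();
  for (size_t i = 0; i < n; ++i) if (q[i] <= 0) p[i] = 0;
  return dx;
}

// [[Rcpp::export]]
List cpp_inorm_fwd(NumericVector x, IntegerVector dims, NumericVector g,
                   NumericVector b, double eps) {
  const int N = dims[0] * dims[1] * dims[2], C = dims[3];
  NumericVector y((size_t)N * C), xhat((size_t)N * C), inv(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * N;
    double mu = 0;
    for (int i = 0; i < N; ++i) mu += xc[i];
    mu /= N;
    double var = 0;
    for (int i = 0; i < N; ++i) { double d = xc[i] - mu; var += d * d; }
    var /= N;
    const double iv = 1.0 / std::sqrt(var + eps);
    inv[c] = iv;
    double* xh = xhat.begin() + (size_t)c * N;
    double* yc = y.begin() + (size_t)c * N;
    const double gc = g[c], bc = b[c];
    for (int i = 0; i < N; ++i) {
      xh[i] = (xc[i] - mu) * iv;
      yc[i] = xh[i] * gc + bc;
    }
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_inorm_bwd(NumericVector dy, NumericVector xhat, NumericVector inv,
                   NumericVector g, IntegerVector dims) {
  const int N = dims[0] * dims[1] * dims[2], C = dims[3];
  NumericVector dx((size_t)N * C), dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.begin() + (size_t)c * N;
    const double* xh = xhat.begin() + (size_t)c * N;
    double sdg = 0, sdb = 0;
    for (int i = 0; i < N; ++i) { sdg += dyc[i] * xh[i]; sdb += dyc[i]; }
    dg[c] = sdg; db[c] = sdb;
    const double gc = g[c], m1 = gc * sdb / N, m2 = gc * sdg / N;
    double* dxc = dx.begin() + (size_t)c * N;
    const double ivc = inv[c];
    for (int i = 0; i < N; ++i)
      dxc[i] = (dyc[i] * gc - m1 - xh[i] * m2) * ivc;
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// ---- down2 (k2 s2) ----------------------------------------------------

static arma::mat gather_blocks_in(const double* x, int d1, int d2, int d3,
                                  int ci) {
  // x lives on the fine grid (d1,d2,d3); rows index coarse voxels
  const int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  const int Nf = d1 * d2 * d3, Nc = e1 * e2 * e3;
  arma::mat P(Nc, 8 * ci);
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + (size_t)c * Nf;
    for (int az = 0; az < 2; ++az)
      for (int ay = 0; ay < 2; ++ay)
        for (int ax = 0; ax < 2; ++ax) {
          double* col = P.colptr(c * 8 + az * 4 + ay * 2 + ax);
          size_t q = 0;
          for (int k = 0; k < e3; ++k)
            for (int j = 0; j < e2; ++j) {
              const double* src =
                  xc + (size_t)((2 * k + az) * d2 + (2 * j + ay)) * d1 + ax;
              for (int i = 0; i < e1; ++i) col[q++] = src[2 * i];
            }
        }
  }
  return P;
}

static void scatter_blocks_out(const arma::mat& M, double* y, int d1, int d2,
                               int d3, int ci, bool accumulate) {
  // inverse of gather_blocks_in: M is (Nc x 8*ci), y on the fine grid
  const int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  const int Nf = d1 * d2 * d3;
  if (!accumulate) std::fill(y, y + (size_t)Nf * ci, 0.0);
  for (int c = 0; c < ci; ++c) {
    double* yc = y + (size_t)c * Nf;
    for (int az = 0; az < 2; ++az)
      for (int ay = 0; ay < 2; ++ay)
        for (int ax = 0; ax < 2; ++ax) {
          const double* col = M.colptr(c * 8 + az * 4 + ay * 2 + ax);
          size_t q = 0;
          for (int k = 0; k < e3; ++k)
            for (int j = 0; j < e2; ++j) {
              double* dst =
                  yc + (size_t)((2 * k + az) * d2 + (2 * j + ay)) * d1 + ax;
              for (int i = 0; i < e1; ++i) dst[2 * i] = col[q++];
            }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_down2_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix w, NumericVector b) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ci = dims[3];
  const int Nc = (d1 / 2) * (d2 / 2) * (d3 / 2), co = w.ncol();
  arma::mat P = gather_blocks_in(x.begin(), d1, d2, d3, ci);
  arma::mat W = as_mat_view(NumericVector(w), 8 * ci, co);
  NumericVector y((size_t)Nc * co);
  arma::mat Y(y.begin(), Nc, co, false, true);
  Y = P * W;
  for (int c = 0; c < co; ++c) Y.col(c) += b[c];
  y.attr("dim") = IntegerVector::create(d1 / 2, d2 / 2, d3 / 2, co);
  return y;
}

// [[Rcpp::export]]
List cpp_down2_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                   NumericVector dy) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ci = dims[3];
  const int Nc = (d1 / 2) * (d2 / 2) * (d3 / 2), co = w.ncol();
  arma::mat P = gather_blocks_in(x.begin(), d1, d2, d3, ci);
  arma::mat W = as_mat_view(NumericVector(w), 8 * ci, co);
  arma::mat dY = as_mat_view(dy, Nc, co);
  NumericMatrix dw(8 * ci, co);
  arma::mat dWv(dw.begin(), 8 * ci, co, false, true);
  dWv = P.t() * dY;
  arma::mat Pg = dY * W.t();
  NumericVector dx((size_t)d1 * d2 * d3 * ci);
  scatter_blocks_out(Pg, dx.begin(), d1, d2, d3, ci, false);
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, ci);
  NumericVector db(co);
  for (int c = 0; c < co; ++c) db[c] = arma::accu(dY.col(c));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- up2 (transposed k2 s2) -------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_up2_fwd(NumericVector x, IntegerVector dims,
                          NumericMatrix w, NumericVector b) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ci = dims[3];
  const int Nin = d1 * d2 * d3;
  const int co = w.ncol() / 8;
  const int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  arma::mat X = as_mat_view(x, Nin, ci);
  arma::mat W = as_mat_view(NumericVector(w), ci, 8 * co);
  arma::mat M = X * W;  // (Nin x 8co)
  NumericVector y((size_t)o1 * o2 * o3 * co);
  scatter_blocks_out(M, y.begin(), o1, o2, o3, co, false);
  arma::mat Y(y.begin(), (size_t)o1 * o2 * o3, co, false, true);
  for (int c = 0; c < co; ++c) Y.col(c) += b[c];
  y.attr("dim") = IntegerVector::create(o1, o2, o3, co);
  return y;
}

// [[Rcpp::export]]
List cpp_up2_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                 NumericVector dy) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ci = dims[3];
  const int Nin = d1 * d2 * d3;
  const int co = w.ncol() / 8;
  const int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  const int Nout = o1 * o2 * o3;
  arma::mat X = as_mat_view(x, Nin, ci);
  arma::mat W = as_mat_view(NumericVector(w), ci, 8 * co);
  arma::mat G = gather_blocks_in(dy.begin(), o1, o2, o3, co);  // (Nin x 8co)
  NumericMatrix dw(ci, 8 * co);
  arma::mat dWv(dw.begin(), ci, 8 * co, false, true);
  dWv = X.t() * G;
  NumericVector dx((size_t)Nin * ci);
  arma::mat dX(dx.begin(), Nin, ci, false, true);
  dX = G * W.t();
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, ci);
  arma::mat dY = as_mat_view(dy, Nout, co);
  NumericVector db(co);
  for (int c = 0; c < co; ++c) db[c] = arma::accu(dY.col(c));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
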