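// 3x3x3 convolution (stride 1, zero padding 1) evaluated as 27 offset-wise
// BLAS gemms against a small reused shift buffer, so no im2col matrix is
// ever materialized. Layout contract (shared with the R layer code):
// activations are (X, Y, Z, C) column-major arrays; the weight matrix has
// 27*C rows ordered offset-major (dx fastest, then dy, dz), channel minor
// within each offset: row = o*C + c.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

namespace {

// buf[, c] = x shifted by offset (dx, dy, dz), zero outside the grid.
void fill_shift(const double *px, double *buf, int X, int Y, int Z, int C,
                int dx, int dy, int dz) {
  const R_xlen_t V = (R_xlen_t)X * Y * Z;
  for (int c = 0; c < C; ++c) {
    double *dst = buf + (R_xlen_t)c * V;
    const double *src = px + (R_xlen_t)c * V;
    for (int z = 0; z < Z; ++z) {
      const int sz = z + dz;
      if (sz < 0 || sz >= Z) {
        std::fill(dst, dst + (R_xlen_t)X * Y, 0.0);
        dst += (R_xlen_t)X * Y;
        continue;
      }
      for (int y = 0; y < Y; ++y) {
        const int sy = y + dy;
        if (sy < 0 || sy >= Y) {
          std::fill(dst, dst + X, 0.0);
          dst += X;
          continue;
        }
        const double *s = src + ((R_xlen_t)sz * Y + sy) * X + dx;
        const int x0 = (dx < 0) ? 1 : 0;
        const int x1 = (dx > 0) ? X - 1 : X;
        if (x0 > 0) dst[0] = 0.0;
        if (x1 < X) dst[X - 1] = 0.0;
        std::copy(s + x0, s + x1, dst + x0);
        dst += X;
      }
    }
  }
}

// dst(v + offset) += t(v): adjoint of fill_shift's gather.
void scatter_shift(const double *t, double *dst0, int X, int Y, int Z, int C,
                   int dx, int dy, int dz) {
  const R_xlen_t V = (R_xlen_t)X * Y * Z;
  for (int c = 0; c < C; ++c) {
    const double *src = t + (R_xlen_t)c * V;
    double *dst = dst0 + (R_xlen_t)c * V;
    for (int z = 0; z < Z; ++z) {
      const int sz = z + dz;
      if (sz < 0 || sz >= Z) { src += (R_xlen_t)X * Y; continue; }
      for (int y = 0; y < Y; ++y) {
        const int sy = y + dy;
        if (sy < 0 || sy >= Y) { src += X; continue; }
        double *d = dst + ((R_xlen_t)sz * Y + sy) * X + dx;
        const int x0 = (dx < 0) ? 1 : 0;
        const int x1 = (dx > 0) ? X - 1 : X;
        for (int xx = x0; xx < x1; ++xx) d[xx] += src[xx];
        src += X;
      }
    }
  }
}

}  // namespace

// Forward: out (V x cout) = sum_o shift_o(x) %*% W[o*C + (0..C-1), ].
// [[Rcpp::export]]
NumericMatrix conv3_mm_cpp(NumericVector x, NumericMatrix W,
                           IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int V = X * Y * Z;
  const int cout = W.ncol();
  const int ldw = W.nrow();  // 27 * C
  NumericMatrix out(V, cout);
  std::vector<double> buf((R_xlen_t)V * C);
  const double one = 1.0;
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        fill_shift(REAL(x), buf.data(), X, Y, Z, C, dx, dy, dz);
        F77_CALL(dgemm)("N", "N", &V, &cout, &C, &one, buf.data(), &V,
                        REAL(W) + o * C, &ldw, &one, REAL(out), &V
                        FCONE FCONE);
      }
  return out;
}

// Input gradient: dx (X,Y,Z,C) with dx += shift_o^T(ds %*% W_o^T).
// [[Rcpp::export]]
NumericVector conv3_dx_cpp(NumericMatrix ds, NumericMatrix W,
                           IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int V = X * Y * Z;
  const int cout = W.ncol();
  const int ldw = W.nrow();
  NumericVector dx((R_xlen_t)V * C);
  dx.attr("dim") = dims;
  std::vector<double> tmp((R_xlen_t)V * C);
  const double one = 1.0, zero = 0.0;
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int ddx = -1; ddx <= 1; ++ddx, ++o) {
        F77_CALL(dgemm)("N", "T", &V, &C, &cout, &one, REAL(ds), &V,
                        REAL(W) + o * C, &ldw, &zero, tmp.data(), &V
                        FCONE FCONE);
        scatter_shift(tmp.data(), REAL(dx), X, Y, Z, C, ddx, dy, dz);
      }
  return dx;
}

// Weight gradient: dW[o*C + (0..C-1), ] = shift_o(x)^T %*% ds.
// [[Rcpp::export]]
NumericMatrix conv3_dw_cpp(NumericVector x, NumericMatrix ds,
                           IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int V = X * Y * Z;
  const int cout = ds.ncol();
  const int ldw = 27 * C;
  NumericMatrix dW(ldw, cout);
  std::vector<double> buf((R_xlen_t)V * C);
  const double one = 1.0, zero = 0.0;
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        fill_shift(REAL(x), buf.data(), X, Y, Z, C, dx, dy, dz);
        F77_CALL(dgemm)("T", "N", &C, &cout, &V, &one, buf.data(), &V,
                        REAL(ds), &V, &zero, REAL(dW) + o * C, &ldw
                        FCONE FCONE);
      }
  return dW;
}
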