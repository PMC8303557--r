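#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <vector>
using namespace Rcpp;

// All image tensors are R arrays in column-major order.
// Feature maps: (H, W, C, N); conv weights: (kh, kw, C_in, C_out).
// Convolutions go through im2col + BLAS dgemm.

// Fill col (K x M), K = kh*kw*C, M = OH*OW, for sample n. Out-of-image
// positions (zero padding) become 0.
static void im2col(const double *X, int H, int W, int C, R_xlen_t xoff,
                   int kh, int kw, int stride, int pad, int OH, int OW,
                   double *col) {
  const int K = kh * kw * C;
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh) {
      double *dst = col + (R_xlen_t)K * (oh + (R_xlen_t)OH * ow);
      const int h0 = oh * stride - pad, w0 = ow * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double *xc = X + xoff + (R_xlen_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          const int wc = w0 + j;
          if (wc < 0 || wc >= W) {
            for (int i = 0; i < kh; ++i) *dst++ = 0.0;
          } else {
            const double *xcol = xc + (R_xlen_t)H * wc;
            for (int i = 0; i < kh; ++i) {
              const int hr = h0 + i;
              *dst++ = (hr < 0 || hr >= H) ? 0.0 : xcol[hr];
            }
          }
        }
      }
    }
}

// Scatter-add of dcol (K x M) back into dX for sample n.
static void col2im(const double *col, int H, int W, int C, R_xlen_t xoff,
                   int kh, int kw, int stride, int pad, int OH, int OW,
                   double *DX) {
  const int K = kh * kw * C;
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh) {
      const double *src = col + (R_xlen_t)K * (oh + (R_xlen_t)OH * ow);
      const int h0 = oh * stride - pad, w0 = ow * stride - pad;
      for (int c = 0; c < C; ++c) {
        double *xc = DX + xoff + (R_xlen_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          const int wc = w0 + j;
          if (wc < 0 || wc >= W) { src += kh; continue; }
          double *xcol = xc + (R_xlen_t)H * wc;
          for (int i = 0; i < kh; ++i) {
            const int hr = h0 + i;
            if (hr >= 0 && hr < H) xcol[hr] += src[i];
          }
          src += kh;
        }
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, M = OH * OW;
  NumericVector y((R_xlen_t)M * F * N);
  y.attr("dim") = IntegerVector::create(OH, OW, F, N);
  std::vector<double> col((R_xlen_t)K * M);
  const double *X = x.begin(), *Wt = w.begin();
  double *Y = y.begin();
  const double one = 1.0, zero = 0.0;
  int bM = M, bF = F, bK = K;
  for (int n = 0; n < N; ++n) {
    im2col(X, H, W, C, (R_xlen_t)H * W * C * n, kh, kw, stride, pad, OH, OW,
           col.data());
    // y_n (M x F) = t(col) (M x K) %*% Wt (K x F)
    double *Yn = Y + (R_xlen_t)M * F * n;
    F77_CALL(dgemm)("T", "N", &bM, &bF, &bK, &one, col.data(), &bK, Wt, &bK,
                    &zero, Yn, &bM FCONE FCONE);
    for (int f = 0; f < F; ++f) {
      const double bf = b[f];
      double *yf = Yn + (R_xlen_t)M * f;
      for (int m = 0; m < M; ++m) yf[m] += bf;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int OH = yd[0], OW = yd[1];
  const int K = kh * kw * C, M = OH * OW;
  NumericVector dx((R_xlen_t)H * W * C * N), dw(w.size()), db(F);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  std::vector<double> col((R_xlen_t)K * M), dcol((R_xlen_t)K * M);
  const double *X = x.begin(), *Wt = w.begin(), *DY = dy.begin();
  double *DX = dx.begin(), *DW = dw.begin(), *DB = db.begin();
  const double one = 1.0, zero = 0.0;
  int bM = M, bF = F, bK = K;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t xoff = (R_xlen_t)H * W * C * n;
    const double *DYn = DY + (R_xlen_t)M * F * n;  // (M x F)
    im2col(X, H, W, C, xoff, kh, kw, stride, pad, OH, OW, col.data());
    // dW (K x F) += col (K x M) %*% dy_n (M x F)
    F77_CALL(dgemm)("N", "N", &bK, &bF, &bM, &one, col.data(), &bK, DYn, &bM,
                    &one, DW, &bK FCONE FCONE);
    // dcol (K x M) = Wt (K x F) %*% t(dy_n) (F x M)
    F77_CALL(dgemm)("N", "T", &bK, &bM, &bF, &one, Wt, &bK, DYn, &bM,
                    &zero, dcol.data(), &bK FCONE FCONE);
    col2im(dcol.data(), H, W, C, xoff, kh, kw, stride, pad, OH, OW, DX);
    for (int f = 0; f < F; ++f) {
      const double *dyf = DYn + (R_xlen_t)M * f;
      double acc = 0.0;
      for (int m = 0; m < M; ++m) acc += dyf[m];
      DB[f] += acc;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling; out-of-bounds positions (implicit -Inf padding) are skipped.
// idx holds 1-based linear indices into x for the winning positions.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int size, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int OH = (H + 2 * pad - size) / stride + 1;
  const int OW = (W + 2 * pad - size) / stride + 1;
  NumericVector y((R_xlen_t)OH * OW * C * N);
  IntegerVector idx((R_xlen_t)OH * OW * C * N);
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  const double *X = x.begin();
  double *Y = y.begin();
  int *ID = idx.begin();
  R_xlen_t k = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          const int h0 = oh * stride - pad, w0 = ow * stride - pad;
          for (int j = 0; j < size; ++j) {
            const int wc = w0 + j;
            if (wc < 0 || wc >= W) continue;
            for (int i = 0; i < size; ++i) {
              const int hr = h0 + i;
              if (hr < 0 || hr >= H) continue;
              const R_xlen_t xi = hr + (R_xlen_t)H * (wc + (R_xlen_t)W * (c + (R_xlen_t)C * n));
              if (X[xi] > best) { best = X[xi]; besti = xi; }
            }
          }
          // column-major write order matches loop nesting per (c, n) panel
          const R_xlen_t yi = oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * (c + (R_xlen_t)C * n));
          Y[yi] = best;
          ID[yi] = (int)(besti + 1);
          ++k;
        }
  (void)k;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double *DX = dx.begin();
  const double *DY = dy.begin();
  const int *ID = idx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) DX[ID[i] - 1] += DY[i];
  return dx;
}

static inline double bilinear_at(const double *M, int H, int W, double r, double c) {
  // replicate border (clamp sample coordinates)
  if (r < 0) r = 0; if (r > H - 1) r = H - 1;
  if (c < 0) c = 0; if (c > W - 1) c = W - 1;
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  const int r1 = r0 < H - 1 ? r0 + 1 : r0, c1 = c0 < W - 1 ? c0 + 1 : c0;
  const double fr = r - r0, fc = c - c0;
  const double v00 = M[r0 + (R_xlen_t)H * c0], v10 = M[r1 + (R_xlen_t)H * c0];
  const double v01 = M[r0 + (R_xlen_t)H * c1], v11 = M[r1 + (R_xlen_t)H * c1];
  return (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
         (1 - fr) * fc * v01 + fr * fc * v11;
}

// Bilinear resize of a 2-D matrix using half-pixel centre alignment.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int oh, int ow) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(oh, ow);
  const double sr = (double)H / oh, sc = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    const double c = (j + 0.5) * sc - 0.5;
    for (int i = 0; i < oh; ++i) {
      const double r = (i + 0.5) * sr - 0.5;
      y(i, j) = bilinear_at(x.begin(), H, W, r, c);
    }
  }
  return y;
}

// Rotate a matrix about its centre by `angle` degrees (counter-clockwise in
// image coordinates), bilinear sampling, replicate border, same output size.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_bilinear(NumericMatrix x, double angle) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  const double th = angle * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double rc = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double dr = i - rc, dc = j - cc;
      // inverse mapping: rotate destination offset by -angle
      const double sr = ct * dr + st * dc + rc;
      const double sc = -st * dr + ct * dc + cc;
      y(i, j) = bilinear_at(x.begin(), H, W, sr, sc);
    }
  return y;
}
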