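// Low-level CPU kernels for the CNN toolkit. Convolutions (2D/3D, stride
// 1, zero padding) are implemented as im2col + BLAS dgemm so the heavy
// lifting runs at matrix-multiplication speed; pooling and the stride-1
// max filters keep argmax bookkeeping so losses can route gradients.
// All tensors are column-major R arrays with the channel last.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>
#include <memory>
using namespace Rcpp;

static IntegerVector dims(const NumericVector &x) {
  return as<IntegerVector>(x.attr("dim"));
}

static void dgemm_(bool ta, bool tb, int M, int N, int K, const double *A,
                   int lda, const double *B, int ldb, double *C, int ldc,
                   double beta = 0.0) {
  const char *cta = ta ? "T" : "N", *ctb = tb ? "T" : "N";
  double one = 1.0;
  F77_CALL(dgemm)(cta, ctb, &M, &N, &K, &one, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// ---------------------------------------------------------------------- 2D

static void im2col2d(const double *x, int H, int W, int C, int kh, int kw,
                     int pad, int Ho, int Wo, double *col) {
  size_t n = (size_t)Ho * Wo;
  for (int ci = 0; ci < C; ++ci)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        double *dst = col + n * (i + (size_t)kh * (j + (size_t)kw * ci));
        const double *src = x + (size_t)H * W * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          double *d2 = dst + (size_t)Ho * wo;
          int wi = wo - pad + j;
          if (wi < 0 || wi >= W) { std::memset(d2, 0, Ho * sizeof(double)); continue; }
          const double *s2 = src + (size_t)H * wi;
          int ho0 = std::max(0, pad - i);
          int ho1 = std::min(Ho, H + pad - i);
          for (int ho = 0; ho < ho0; ++ho) d2[ho] = 0.0;
          for (int ho = ho1; ho < Ho; ++ho) d2[ho] = 0.0;
          if (ho1 > ho0)
            std::memcpy(d2 + ho0, s2 + (ho0 - pad + i),
                        (size_t)(ho1 - ho0) * sizeof(double));
        }
      }
}

static void col2im2d(const double *col, int H, int W, int C, int kh, int kw,
                     int pad, int Ho, int Wo, double *x) {
  size_t n = (size_t)Ho * Wo;
  for (int ci = 0; ci < C; ++ci)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const double *src = col + n * (i + (size_t)kh * (j + (size_t)kw * ci));
        double *dst = x + (size_t)H * W * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo - pad + j;
          if (wi < 0 || wi >= W) continue;
          const double *s2 = src + (size_t)Ho * wo;
          double *d2 = dst + (size_t)H * wi;
          int ho0 = std::max(0, pad - i);
          int ho1 = std::min(Ho, H + pad - i);
          for (int ho = ho0; ho < ho1; ++ho) d2[ho - pad + i] += s2[ho];
        }
      }
}

// x: (H,W,Ci), w: (kh,kw,Ci,Co), b: Co. Output (H+2p-kh+1, W+2p-kw+1, Co).
// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  IntegerVector xd = dims(x), wd = dims(w);
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  size_t n = (size_t)Ho * Wo, m = (size_t)kh * kw * C;
  std::unique_ptr<double[]> col(new double[n * m]);
  im2col2d(REAL(x), H, W, C, kh, kw, pad, Ho, Wo, col.get());
  NumericVector y((R_xlen_t)(n * Co));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  dgemm_(false, false, (int)n, Co, (int)m, col.get(), (int)n, REAL(w),
         (int)m, REAL(y), (int)n);
  double *yp = REAL(y);
  for (int co = 0; co < Co; ++co) {
    double bv = b[co];
    for (size_t i = 0; i < n; ++i) yp[n * co + i] += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int pad) {
  IntegerVector xd = dims(x), wd = dims(w), yd = dims(dy);
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int Ho = yd[0], Wo = yd[1];
  size_t n = (size_t)Ho * Wo, m = (size_t)kh * kw * C;
  std::unique_ptr<double[]> col(new double[n * m]);
  im2col2d(REAL(x), H, W, C, kh, kw, pad, Ho, Wo, col.get());
  NumericVector dw(w.size()), db(Co), dx(x.size());
  dw.attr("dim") = wd;
  dx.attr("dim") = xd;
  dgemm_(true, false, (int)m, Co, (int)n, col.get(), (int)n, REAL(dy),
         (int)n, REAL(dw), (int)m);
  const double *dyp = REAL(dy);
  for (int co = 0; co < Co; ++co) {
    double s = 0;
    for (size_t i = 0; i < n; ++i) s += dyp[n * co + i];
    db[co] = s;
  }
  std::unique_ptr<double[]> dcol(new double[n * m]);
  dgemm_(false, true, (int)n, (int)m, Co, REAL(dy), (int)n, REAL(w), (int)m,
         dcol.get(), (int)n);
  col2im2d(dcol.get(), H, W, C, kh, kw, pad, Ho, Wo, REAL(dx));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------- 3D

static void im2col3d(const double *x, int X, int Y, int Z, int C, int k,
                     int pad, int Xo, int Yo, int Zo, double *col) {
  size_t n = (size_t)Xo * Yo * Zo;
  for (int ci = 0; ci < C; ++ci)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          double *dst = col + n * (kx + (size_t)k * (ky + (size_t)k * (kz + (size_t)k * ci)));
          const double *src = x + (size_t)X * Y * Z * ci;
          for (int zo = 0; zo < Zo; ++zo) {
            int zi = zo - pad + kz;
            for (int yo = 0; yo < Yo; ++yo) {
              double *d2 = dst + (size_t)Xo * (yo + (size_t)Yo * zo);
              int yi = yo - pad + ky;
              if (zi < 0 || zi >= Z || yi < 0 || yi >= Y) {
                std::memset(d2, 0, Xo * sizeof(double));
                continue;
              }
              const double *s2 = src + (size_t)X * (yi + (size_t)Y * zi);
              int xo0 = std::max(0, pad - kx);
              int xo1 = std::min(Xo, X + pad - kx);
              for (int xo = 0; xo < xo0; ++xo) d2[xo] = 0.0;
              for (int xo = xo1; xo < Xo; ++xo) d2[xo] = 0.0;
              if (xo1 > xo0)
                std::memcpy(d2 + xo0, s2 + (xo0 - pad + kx),
                            (size_t)(xo1 - xo0) * sizeof(double));
            }
          }
        }
}

static void col2im3d(const double *col, int X, int Y, int Z, int C, int k,
                     int pad, int Xo, int Yo, int Zo, double *x) {
  size_t n = (size_t)Xo * Yo * Zo;
  for (int ci = 0; ci < C; ++ci)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const double *src = col + n * (kx + (size_t)k * (ky + (size_t)k * (kz + (size_t)k * ci)));
          double *dst = x + (size_t)X * Y * Z * ci;
          for (int zo = 0; zo < Zo; ++zo) {
            int zi = zo - pad + kz;
            if (zi < 0 || zi >= Z) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              int yi = yo - pad + ky;
              if (yi < 0 || yi >= Y) continue;
              const double *s2 = src + (size_t)Xo * (yo + (size_t)Yo * zo);
              double *d2 = dst + (size_t)X * (yi + (size_t)Y * zi);
              int xo0 = std::max(0, pad - kx);
              int xo1 = std::min(Xo, X + pad - kx);
              for (int xo = xo0; xo < xo1; ++xo) d2[xo - pad + kx] += s2[xo];
            }
          }
        }
}

// x: (X,Y,Z,Ci), w: (k,k,k,Ci,Co), b: Co, zero pad, stride 1.
// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  IntegerVector xd = dims(x), wd = dims(w);
  int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  int k = wd[0], Co = wd[4];
  int Xo = X + 2 * pad - k + 1, Yo = Y + 2 * pad - k + 1, Zo = Z + 2 * pad - k + 1;
  size_t n = (size_t)Xo * Yo * Zo, m = (size_t)k * k * k * C;
  std::unique_ptr<double[]> col(new double[n * m]);
  im2col3d(REAL(x), X, Y, Z, C, k, pad, Xo, Yo, Zo, col.get());
  NumericVector y((R_xlen_t)(n * Co));
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  dgemm_(false, false, (int)n, Co, (int)m, col.get(), (int)n, REAL(w),
         (int)m, REAL(y), (int)n);
  double *yp = REAL(y);
  for (int co = 0; co < Co; ++co) {
    double bv = b[co];
    for (size_t i = 0; i < n; ++i) yp[n * co + i] += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int pad) {
  IntegerVector xd = dims(x), wd = dims(w), yd = dims(dy);
  int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  int k = wd[0], Co = wd[4];
  int Xo = yd[0], Yo = yd[1], Zo = yd[2];
  size_t n = (size_t)Xo * Yo * Zo, m = (size_t)k * k * k * C;
  std::unique_ptr<double[]> col(new double[n * m]);
  im2col3d(REAL(x), X, Y, Z, C, k, pad, Xo, Yo, Zo, col.get());
  NumericVector dw(w.size()), db(Co), dx(x.size());
  dw.attr("dim") = wd;
  dx.attr("dim") = xd;
  dgemm_(true, false, (int)m, Co, (int)n, col.get(), (int)n, REAL(dy),
         (int)n, REAL(dw), (int)m);
  const double *dyp = REAL(dy);
  for (int co = 0; co < Co; ++co) {
    double s = 0;
    for (size_t i = 0; i < n; ++i) s += dyp[n * co + i];
    db[co] = s;
  }
  std::unique_ptr<double[]> dcol(new double[n * m]);
  dgemm_(false, true, (int)n, (int)m, Co, REAL(dy), (int)n, REAL(w), (int)m,
         dcol.get(), (int)n);
  col2im3d(dcol.get(), X, Y, Z, C, k, pad, Xo, Yo, Zo, REAL(dx));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ------------------------------------------------------------------ pooling

// 2x2 max pooling, stride 2; 1-based argmax indices into the input.
// [[Rcpp::export]]
List maxpool2d_fwd_cpp(NumericVector x) {
  IntegerVector xd = dims(x);
  int H = xd[0], W = xd[1], C = xd[2];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double *xp = REAL(x);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        size_t bi = 0;
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            size_t ii = (2 * ho + i) + (size_t)H * ((2 * wo + j) + (size_t)W * c);
            if (xp[ii] > best) { best = xp[ii]; bi = ii; }
          }
        size_t oi = ho + (size_t)Ho * (wo + (size_t)Wo * c);
        y[oi] = best;
        idx[oi] = (int)(bi + 1);
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx,
                              IntegerVector in_dim) {
  R_xlen_t n = 1;
  for (int i = 0; i < in_dim.size(); ++i) n *= in_dim[i];
  NumericVector dx(n);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// 2x2x2 max pooling, stride 2 (4D input X,Y,Z,C).
// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x) {
  IntegerVector xd = dims(x);
  int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * C);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  const double *xp = REAL(x);
  for (int c = 0; c < C; ++c)
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo) {
          double best = R_NegInf;
          size_t bi = 0;
          for (int k = 0; k < 2; ++k)
            for (int j = 0; j < 2; ++j)
              for (int i = 0; i < 2; ++i) {
                size_t ii = (2 * xo + i) +
                  (size_t)X * ((2 * yo + j) +
                  (size_t)Y * ((2 * zo + k) + (size_t)Z * c));
                if (xp[ii] > best) { best = xp[ii]; bi = ii; }
              }
          size_t oi = xo + (size_t)Xo * (yo + (size_t)Yo * (zo + (size_t)Zo * c));
          y[oi] = best;
          idx[oi] = (int)(bi + 1);
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// ------------------------------------------------- transposed convolution

// Transposed convolution, kernel 2x2, stride 2: x (H,W,Ci) -> (2H,2W,Co).
// Output windows do not overlap, so this is one dgemm plus a scatter.
// [[Rcpp::export]]
NumericVector upconv2d_fwd_cpp(NumericVector x, NumericVector w,
                               NumericVector b) {
  IntegerVector xd = dims(x), wd = dims(w);
  int H = xd[0], W = xd[1], C = xd[2], Co = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  size_t n = (size_t)H * W;
  // B: C x (4*Co), column order (i + 2j + 4co)
  std::vector<double> B((size_t)C * 4 * Co), Cmat(n * 4 * Co);
  const double *wp = REAL(w);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i)
          B[ci + (size_t)C * (i + 2 * j + 4 * co)] =
            wp[i + 2 * (j + 2 * (ci + (size_t)C * co))];
  dgemm_(false, false, (int)n, 4 * Co, C, REAL(x), (int)n, B.data(), C,
         Cmat.data(), (int)n);
  NumericVector y((R_xlen_t)Ho * Wo * Co);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  double *yp = REAL(y);
  for (int co = 0; co < Co; ++co) {
    double bv = b[co];
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i) {
        const double *src = Cmat.data() + n * (i + 2 * j + 4 * co);
        for (int wi = 0; wi < W; ++wi)
          for (int hi = 0; hi < H; ++hi)
            yp[(2 * hi + i) + (size_t)Ho * ((2 * wi + j) + (size_t)Wo * co)] =
              src[hi + (size_t)H * wi] + bv;
      }
  }
  return y;
}

// [[Rcpp::export]]
List upconv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = dims(x), wd = dims(w);
  int H = xd[0], W = xd[1], C = xd[2], Co = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  size_t n = (size_t)H * W;
  // gather dy into dCmat (n x 4Co)
  std::vector<double> dCmat(n * 4 * Co);
  NumericVector db(Co);
  const double *dyp = REAL(dy);
  for (int co = 0; co < Co; ++co) {
    double s = 0;
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i) {
        double *dst = dCmat.data() + n * (i + 2 * j + 4 * co);
        for (int wi = 0; wi < W; ++wi)
          for (int hi = 0; hi < H; ++hi) {
            double g = dyp[(2 * hi + i) + (size_t)Ho * ((2 * wi + j) + (size_t)Wo * co)];
            dst[hi + (size_t)H * wi] = g;
            s += g;
          }
      }
    db[co] = s;
  }
  // B as in forward
  std::vector<double> B((size_t)C * 4 * Co), dB((size_t)C * 4 * Co);
  const double *wp = REAL(w);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i)
          B[ci + (size_t)C * (i + 2 * j + 4 * co)] =
            wp[i + 2 * (j + 2 * (ci + (size_t)C * co))];
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  dgemm_(false, true, (int)n, C, 4 * Co, dCmat.data(), (int)n, B.data(), C,
         REAL(dx), (int)n);
  dgemm_(true, false, C, 4 * Co, (int)n, REAL(x), (int)n, dCmat.data(),
         (int)n, dB.data(), C);
  double *dwp = REAL(dw);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i)
          dwp[i + 2 * (j + 2 * (ci + (size_t)C * co))] =
            dB[ci + (size_t)C * (i + 2 * j + 4 * co)];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ------------------------------------------------------------- max filters

// Stride-1 centered max filter on a 2D matrix, window k (odd), windows
// clipped at the borders. Returns filtered values and 1-based argmax.
// [[Rcpp::export]]
List maxfilt2d_fwd_cpp(NumericMatrix x, int k) {
  int H = x.nrow(), W = x.ncol(), r = (k - 1) / 2;
  NumericMatrix y(H, W);
  IntegerMatrix idx(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double best = R_NegInf;
      int bi = 0;
      int j0 = std::max(0, w - r), j1 = std::min(W - 1, w + r);
      int i0 = std::max(0, h - r), i1 = std::min(H - 1, h + r);
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double v = x(i, j);
          if (v > best) { best = v; bi = i + H * j; }
        }
      y(h, w) = best;
      idx(h, w) = bi + 1;
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxfilt2d_bwd_cpp(NumericMatrix dy, IntegerMatrix idx) {
  int H = dy.nrow(), W = dy.ncol();
  NumericMatrix dx(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      dx[idx(h, w) - 1] += dy(h, w);
  return dx;
}

// ------------------------------------------------------- trilinear shift

// Trilinear sample of a replicate-padded 3D array at a constant offset:
// out[v] = arrp[v + p + off] interpolated. `d` is the unpadded shape.
// [[Rcpp::export]]
NumericVector shift3d_cpp(NumericVector arrp, IntegerVector d, int p,
                          NumericVector off) {
  int X = d[0], Y = d[1], Z = d[2];
  int Xp = X + 2 * p, Yp = Y + 2 * p;
  int f0 = (int)std::floor(off[0]), f1 = (int)std::floor(off[1]),
      f2 = (int)std::floor(off[2]);
  double r0 = off[0] - f0, r1 = off[1] - f1, r2 = off[2] - f2;
  NumericVector out((R_xlen_t)X * Y * Z);
  out.attr("dim") = d;
  const double *a = REAL(arrp);
  double *o = REAL(out);
  std::memset(o, 0, (size_t)X * Y * Z * sizeof(double));
  for (int cz = 0; cz < 2; ++cz)
    for (int cy = 0; cy < 2; ++cy)
      for (int cx = 0; cx < 2; ++cx) {
        double w = (cx ? r0 : 1 - r0) * (cy ? r1 : 1 - r1) *
                   (cz ? r2 : 1 - r2);
        if (w == 0.0) continue;
        for (int z = 0; z < Z; ++z) {
          size_t zoff = (size_t)Xp * Yp * (z + p + f2 + cz);
          for (int y = 0; y < Y; ++y) {
            const double *src = a + zoff + (size_t)Xp * (y + p + f1 + cy) +
                                (p + f0 + cx);
            double *dst = o + (size_t)X * (y + (size_t)Y * z);
            for (int x = 0; x < X; ++x) dst[x] += w * src[x];
          }
        }
      }
  return out;
}

// Full 3D-LBP accumulation core: for each direction j, trilinearly sample
// the padded volume at +off[j,], subtract the center value, update raw
// moments and accumulate the spherical-harmonic projection.
// Returns coef (N x M), and raw moments m1..m4 (already divided by J).
// [[Rcpp::export]]
List lbp3d_core_cpp(NumericVector arrp, NumericVector ctr, IntegerVector d,
                    int p, NumericMatrix offs, NumericMatrix Y) {
  int X = d[0], Yd = d[1], Z = d[2];
  int Xp = X + 2 * p, Yp = Yd + 2 * p;
  size_t N = (size_t)X * Yd * Z;
  int J = offs.nrow(), M = Y.ncol();
  NumericMatrix coef((R_xlen_t)N, M);
  NumericVector m1(N), m2(N), m3(N), m4(N);
  std::vector<double> f(N);
  const double *a = REAL(arrp), *c = REAL(ctr);
  double *cf = REAL(coef);
  double *p1 = REAL(m1), *p2 = REAL(m2), *p3 = REAL(m3), *p4 = REAL(m4);
  for (int j = 0; j < J; ++j) {
    int f0 = (int)std::floor(offs(j, 0)), f1 = (int)std::floor(offs(j, 1)),
        f2 = (int)std::floor(offs(j, 2));
    double r0 = offs(j, 0) - f0, r1 = offs(j, 1) - f1, r2 = offs(j, 2) - f2;
    std::fill(f.begin(), f.end(), 0.0);
    for (int cz = 0; cz < 2; ++cz)
      for (int cy = 0; cy < 2; ++cy)
        for (int cx = 0; cx < 2; ++cx) {
          double w = (cx ? r0 : 1 - r0) * (cy ? r1 : 1 - r1) *
                     (cz ? r2 : 1 - r2);
          if (w == 0.0) continue;
          for (int z = 0; z < Z; ++z) {
            size_t zoff = (size_t)Xp * Yp * (z + p + f2 + cz);
            for (int y = 0; y < Yd; ++y) {
              const double *src = a + zoff + (size_t)Xp * (y + p + f1 + cy) +
                                  (p + f0 + cx);
              double *dst = f.data() + (size_t)X * (y + (size_t)Yd * z);
              for (int x = 0; x < X; ++x) dst[x] += w * src[x];
            }
          }
        }
    for (size_t i = 0; i < N; ++i) {
      double fv = f[i] - c[i];
      f[i] = fv;
      double f2v = fv * fv;
      p1[i] += fv;
      p2[i] += f2v;
      p3[i] += f2v * fv;
      p4[i] += f2v * f2v;
    }
    for (int m = 0; m < M; ++m) {
      double ym = Y(j, m) / J;
      double *cm = cf + N * m;
      const double *fp = f.data();
      for (size_t i = 0; i < N; ++i) cm[i] += ym * fp[i];
    }
  }
  double invJ = 1.0 / J;
  for (size_t i = 0; i < N; ++i) {
    p1[i] *= invJ; p2[i] *= invJ; p3[i] *= invJ; p4[i] *= invJ;
  }
  return List::create(_["coef"] = coef, _["m1"] = m1, _["m2"] = m2,
                      _["m3"] = m3, _["m4"] = m4);
}
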