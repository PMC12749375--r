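// Numeric kernels for the denoising network: im2col/col2im lowering for
// stride-1 zero-padded 3D/2D convolution (the matrix products run through
// R's BLAS) and 2x ceil-mode max-pooling.
// Arrays are R column-major with channel fastest: x[c + C*(d + D*(h + H*w))].
// The column matrix is (R, N): one column of R = Ci*k^d taps per output
// position, so reads and writes both stream through memory.
#include <Rcpp.h>
#include <cfloat>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, int Ci, int D, int H, int W,
                      int k, int pad) {
  R_xlen_t N = (R_xlen_t)D * H * W;
  int R = Ci * k * k * k;
  NumericMatrix cols(R, N);
  const double *xp = x.begin();
  double *cp = cols.begin();
  for (int wo = 0; wo < W; ++wo)
    for (int ho = 0; ho < H; ++ho)
      for (int dd = 0; dd < D; ++dd) {
        double *col = cp + (R_xlen_t)R * (dd + (R_xlen_t)D * (ho + (R_xlen_t)H * wo));
        for (int kw = 0; kw < k; ++kw) {
          int wi = wo + kw - pad;
          for (int kh = 0; kh < k; ++kh) {
            int hi = ho + kh - pad;
            for (int kd = 0; kd < k; ++kd) {
              int di = dd + kd - pad;
              double *dst = col + Ci * (kd + k * (kh + k * kw));
              if (wi < 0 || wi >= W || hi < 0 || hi >= H || di < 0 || di >= D)
                std::memset(dst, 0, Ci * sizeof(double));
              else
                std::memcpy(dst, xp + (R_xlen_t)Ci *
                            (di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi)),
                            Ci * sizeof(double));
            }
          }
        }
      }
  return cols;
}

// Adjoint of im2col3: scatter-add column gradients back into the input.
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix cols, int Ci, int D, int H, int W,
                      int k, int pad) {
  R_xlen_t N = (R_xlen_t)D * H * W;
  int R = Ci * k * k * k;
  NumericVector gx((R_xlen_t)Ci * N);
  const double *cp = cols.begin();
  double *gp = gx.begin();
  for (int wo = 0; wo < W; ++wo)
    for (int ho = 0; ho < H; ++ho)
      for (int dd = 0; dd < D; ++dd) {
        const double *col = cp + (R_xlen_t)R * (dd + (R_xlen_t)D * (ho + (R_xlen_t)H * wo));
        for (int kw = 0; kw < k; ++kw) {
          int wi = wo + kw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = ho + kh - pad;
            if (hi < 0 || hi >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              int di = dd + kd - pad;
              if (di < 0 || di >= D) continue;
              const double *src = col + Ci * (kd + k * (kh + k * kw));
              double *dst = gp + (R_xlen_t)Ci *
                (di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi));
              for (int ci = 0; ci < Ci; ++ci) dst[ci] += src[ci];
            }
          }
        }
      }
  return gx;
}

// [[Rcpp::export(name = ".im2col2")]]
NumericMatrix im2col2(NumericVector x, int Ci, int H, int W, int k, int pad) {
  R_xlen_t N = (R_xlen_t)H * W;
  int R = Ci * k * k;
  NumericMatrix cols(R, N);
  const double *xp = x.begin();
  double *cp = cols.begin();
  for (int wo = 0; wo < W; ++wo)
    for (int ho = 0; ho < H; ++ho) {
      double *col = cp + (R_xlen_t)R * (ho + (R_xlen_t)H * wo);
      for (int kw = 0; kw < k; ++kw) {
        int wi = wo + kw - pad;
        for (int kh = 0; kh < k; ++kh) {
          int hi = ho + kh - pad;
          double *dst = col + Ci * (kh + k * kw);
          if (wi < 0 || wi >= W || hi < 0 || hi >= H)
            std::memset(dst, 0, Ci * sizeof(double));
          else
            std::memcpy(dst, xp + (R_xlen_t)Ci * (hi + (R_xlen_t)H * wi),
                        Ci * sizeof(double));
        }
      }
    }
  return cols;
}

// [[Rcpp::export(name = ".col2im2")]]
NumericVector col2im2(NumericMatrix cols, int Ci, int H, int W, int k, int pad) {
  R_xlen_t N = (R_xlen_t)H * W;
  int R = Ci * k * k;
  NumericVector gx((R_xlen_t)Ci * N);
  const double *cp = cols.begin();
  double *gp = gx.begin();
  for (int wo = 0; wo < W; ++wo)
    for (int ho = 0; ho < H; ++ho) {
      const double *col = cp + (R_xlen_t)R * (ho + (R_xlen_t)H * wo);
      for (int kw = 0; kw < k; ++kw) {
        int wi = wo + kw - pad;
        if (wi < 0 || wi >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          int hi = ho + kh - pad;
          if (hi < 0 || hi >= H) continue;
          const double *src = col + Ci * (kh + k * kw);
          double *dst = gp + (R_xlen_t)Ci * (hi + (R_xlen_t)H * wi);
          for (int ci = 0; ci < Ci; ++ci) dst[ci] += src[ci];
        }
      }
    }
  return gx;
}

// 2x2x2 max pool, stride 2, ceil mode (trailing odd planes pool over the
// partial window). Returns pooled values and 1-based argmax indices.
// [[Rcpp::export(name = ".maxpool3_fwd")]]
List maxpool3_fwd(NumericVector x, int C, int D, int H, int W) {
  int D2 = (D + 1) / 2, H2 = (H + 1) / 2, W2 = (W + 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(C) * D2 * H2 * W2);
  IntegerVector idx(y.size());
  const double *xp = x.begin();
  for (int wo = 0; wo < W2; ++wo)
    for (int ho = 0; ho < H2; ++ho)
      for (int dd = 0; dd < D2; ++dd)
        for (int c = 0; c < C; ++c) {
          double best = -DBL_MAX; R_xlen_t bi = 0;
          for (int ow = 0; ow < 2; ++ow) {
            int wi = 2 * wo + ow; if (wi >= W) continue;
            for (int oh = 0; oh < 2; ++oh) {
              int hi = 2 * ho + oh; if (hi >= H) continue;
              for (int od = 0; od < 2; ++od) {
                int di = 2 * dd + od; if (di >= D) continue;
                R_xlen_t p = c + (R_xlen_t)C * (di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi));
                if (xp[p] > best) { best = xp[p]; bi = p; }
              }
            }
          }
          R_xlen_t q = c + (R_xlen_t)C * (dd + (R_xlen_t)D2 * (ho + (R_xlen_t)H2 * wo));
          y[q] = best; idx[q] = (int)(bi + 1);
        }
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["dim"] = IntegerVector::create(C, D2, H2, W2));
}

// [[Rcpp::export(name = ".maxpool3_bwd")]]
NumericVector maxpool3_bwd(NumericVector gy, IntegerVector idx, R_xlen_t n_in) {
  NumericVector gx(n_in);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}
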