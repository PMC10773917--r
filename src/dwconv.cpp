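// Depthwise-convolution kernels.
//
// Activations use the package's internal (H, W, N, C) column-major layout.
// The depthwise case has no channel contraction to hand to BLAS, so a naive
// R implementation pays k^2 full-tensor copies per call; these loops visit
// each element once per kernel tap with contiguous inner strides.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".dw_fwd")]]
NumericVector dw_fwd(NumericVector x, IntegerVector xdim, NumericVector w,
                     int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], N = xdim[2], C = xdim[3];
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * N * C);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double *xc = px + (static_cast<R_xlen_t>(c) * N + n) * H * W;
      double *yc = py + (static_cast<R_xlen_t>(c) * N + n) * Ho * Wo;
      for (int j = 0; j < k; ++j) {
        for (int i = 0; i < k; ++i) {
          const double wij = pw[i + k * (j + k * c)];
          if (wij == 0.0) continue;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride + j - pad;
            if (iw < 0 || iw >= W) continue;
            const double *xcol = xc + static_cast<R_xlen_t>(iw) * H;
            double *ycol = yc + static_cast<R_xlen_t>(ow) * Ho;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride + i - pad;
              if (ih < 0 || ih >= H) continue;
              ycol[oh] += wij * xcol[ih];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return y;
}

// [[Rcpp::export(name = ".dw_bwd")]]
List dw_bwd(NumericVector dy, NumericVector x, IntegerVector xdim,
            NumericVector w, int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], N = xdim[2], C = xdim[3];
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector dx(static_cast<R_xlen_t>(H) * W * N * C);
  NumericVector dw(static_cast<R_xlen_t>(k) * k * C);
  const double *px = x.begin(), *pw = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const R_xlen_t xoff = (static_cast<R_xlen_t>(c) * N + n) * H * W;
      const R_xlen_t yoff = (static_cast<R_xlen_t>(c) * N + n) * Ho * Wo;
      for (int j = 0; j < k; ++j) {
        for (int i = 0; i < k; ++i) {
          const double wij = pw[i + k * (j + k * c)];
          double acc = 0.0;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride + j - pad;
            if (iw < 0 || iw >= W) continue;
            const double *xcol = px + xoff + static_cast<R_xlen_t>(iw) * H;
            double *dxcol = pdx + xoff + static_cast<R_xlen_t>(iw) * H;
            const double *dycol = pdy + yoff + static_cast<R_xlen_t>(ow) * Ho;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride + i - pad;
              if (ih < 0 || ih >= H) continue;
              const double g = dycol[oh];
              acc += g * xcol[ih];
              dxcol[ih] += g * wij;
            }
          }
          pdw[i + k * (j + k * c)] += acc;
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(k, k, C);
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
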