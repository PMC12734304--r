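#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Batched feature tensors are stored as R arrays with dim (C, D, H, W, N),
// column-major, so the channel index is the fastest-varying one. Depthwise
// kernels are stored as (k, k, k, C); inside these routines they are
// transposed to channel-fastest order so the inner channel loop is
// contiguous in x, y and the transposed kernel alike.

static inline int out_dim(int in, int k, int stride, int dilation, int pad) {
  int eff = dilation * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// [[Rcpp::export]]
NumericVector dw_conv3d_fwd(NumericVector x, IntegerVector xdim,
                            NumericVector w, int k,
                            int stride, int dilation, int pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int OD = out_dim(D, k, stride, dilation, pad);
  const int OH = out_dim(H, k, stride, dilation, pad);
  const int OW = out_dim(W, k, stride, dilation, pad);
  if (OD < 1 || OH < 1 || OW < 1)
    stop("input (%d x %d x %d) too small for kernel %d at dilation %d",
         D, H, W, k, dilation);
  NumericVector y(static_cast<R_xlen_t>(C) * OD * OH * OW * N);
  // transpose kernel to (C, k, k, k)
  std::vector<double> wt(static_cast<size_t>(C) * k * k * k);
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < k; ++l)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          wt[c + (size_t)C * (i + k * (j + k * l))] =
            w[i + k * (j + k * (l + k * c))];
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          double *yo = py + (R_xlen_t)C * (od + (R_xlen_t)OD * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n)));
          for (int l = 0; l < k; ++l) {
            int iw = ow * stride - pad + dilation * l;
            if (iw < 0 || iw >= W) continue;
            for (int j = 0; j < k; ++j) {
              int ih = oh * stride - pad + dilation * j;
              if (ih < 0 || ih >= H) continue;
              for (int i = 0; i < k; ++i) {
                int id = od * stride - pad + dilation * i;
                if (id < 0 || id >= D) continue;
                const double *xo = px + (R_xlen_t)C * (id + (R_xlen_t)D * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n)));
                const double *wo = &wt[(size_t)C * (i + k * (j + k * l))];
                for (int c = 0; c < C; ++c) yo[c] += wo[c] * xo[c];
              }
            }
          }
        }
  y.attr("dim") = IntegerVector::create(C, OD, OH, OW, N);
  return y;
}

// [[Rcpp::export]]
NumericVector dw_conv3d_bwd_input(NumericVector gy, IntegerVector ydim,
                                  NumericVector w, int k,
                                  int stride, int dilation, int pad,
                                  IntegerVector xdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int OD = ydim[1], OH = ydim[2], OW = ydim[3];
  NumericVector gx(static_cast<R_xlen_t>(C) * D * H * W * N);
  std::vector<double> wt(static_cast<size_t>(C) * k * k * k);
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < k; ++l)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          wt[c + (size_t)C * (i + k * (j + k * l))] =
            w[i + k * (j + k * (l + k * c))];
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          const double *go = pg + (R_xlen_t)C * (od + (R_xlen_t)OD * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n)));
          for (int l = 0; l < k; ++l) {
            int iw = ow * stride - pad + dilation * l;
            if (iw < 0 || iw >= W) continue;
            for (int j = 0; j < k; ++j) {
              int ih = oh * stride - pad + dilation * j;
              if (ih < 0 || ih >= H) continue;
              for (int i = 0; i < k; ++i) {
                int id = od * stride - pad + dilation * i;
                if (id < 0 || id >= D) continue;
                double *xo = px + (R_xlen_t)C * (id + (R_xlen_t)D * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n)));
                const double *wo = &wt[(size_t)C * (i + k * (j + k * l))];
                for (int c = 0; c < C; ++c) xo[c] += wo[c] * go[c];
              }
            }
          }
        }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector dw_conv3d_bwd_weight(NumericVector x, IntegerVector xdim,
                                   NumericVector gy, IntegerVector ydim,
                                   int k, int stride, int dilation, int pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int OD = ydim[1], OH = ydim[2], OW = ydim[3];
  std::vector<double> gwt(static_cast<size_t>(C) * k * k * k, 0.0);
  const double *px = x.begin();
  const double *pg = gy.begin();
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          const double *go = pg + (R_xlen_t)C * (od + (R_xlen_t)OD * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n)));
          for (int l = 0; l < k; ++l) {
            int iw = ow * stride - pad + dilation * l;
            if (iw < 0 || iw >= W) continue;
            for (int j = 0; j < k; ++j) {
              int ih = oh * stride - pad + dilation * j;
              if (ih < 0 || ih >= H) continue;
              for (int i = 0; i < k; ++i) {
                int id = od * stride - pad + dilation * i;
                if (id < 0 || id >= D) continue;
                const double *xo = px + (R_xlen_t)C * (id + (R_xlen_t)D * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n)));
                double *gw = &gwt[(size_t)C * (i + k * (j + k * l))];
                for (int c = 0; c < C; ++c) gw[c] += xo[c] * go[c];
              }
            }
          }
        }
  NumericVector gw(static_cast<R_xlen_t>(k) * k * k * C);
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < k; ++l)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          gw[i + k * (j + k * (l + k * c))] =
            gwt[c + (size_t)C * (i + k * (j + k * l))];
  gw.attr("dim") = IntegerVector::create(k, k, k, C);
  return gw;
}
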