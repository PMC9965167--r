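// Low-level kernels for the multimodal fusion network: 3-D convolution with
// 'same' zero padding and stride 1 (im2col + BLAS gemm) and ceiling-mode 3-D
// max pooling, plus their gradients. 2-D streams reuse the same kernels with
// a depth of 1. The im2col buffer is laid out positions-by-kernel-elements
// (P x K) so fills and scatters run along contiguous memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// gather one sample (H,W,D,C) into col(P, K), K = kh*kw*kd*C, P = H*W*D;
// 'same' zero padding, stride 1; column k holds the shifted image for one
// kernel offset, so writes are contiguous h-runs.
static void im2col(const double* x, int H, int W, int D, int C,
                   int kh, int kw, int kd, arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2, pd = (kd - 1) / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W * D;
    for (int kdi = 0; kdi < kd; ++kdi)
      for (int kwi = 0; kwi < kw; ++kwi)
        for (int khi = 0; khi < kh; ++khi) {
          int k = khi + kh * (kwi + kw * (kdi + kd * c));
          double* ck = col.colptr(k);
          for (int d = 0; d < D; ++d) {
            int ds = d + kdi - pd;
            if (ds < 0 || ds >= D) continue;
            for (int w = 0; w < W; ++w) {
              int ws = w + kwi - pw;
              if (ws < 0 || ws >= W) continue;
              int h0 = std::max(0, ph - khi);
              int h1 = std::min(H, H + ph - khi);
              const double* src = xc + ((size_t)ds * W + ws) * H + (h0 + khi - ph);
              double* dst = ck + ((size_t)d * W + w) * H + h0;
              std::memcpy(dst, src, (h1 - h0) * sizeof(double));
            }
          }
        }
  }
}

// scatter-add the (P x K) column gradient back onto the input gradient
static void col2im(const arma::mat& col, int H, int W, int D, int C,
                   int kh, int kw, int kd, double* gx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2, pd = (kd - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W * D;
    for (int kdi = 0; kdi < kd; ++kdi)
      for (int kwi = 0; kwi < kw; ++kwi)
        for (int khi = 0; khi < kh; ++khi) {
          int k = khi + kh * (kwi + kw * (kdi + kd * c));
          const double* ck = col.colptr(k);
          for (int d = 0; d < D; ++d) {
            int ds = d + kdi - pd;
            if (ds < 0 || ds >= D) continue;
            for (int w = 0; w < W; ++w) {
              int ws = w + kwi - pw;
              if (ws < 0 || ws >= W) continue;
              int h0 = std::max(0, ph - khi);
              int h1 = std::min(H, H + ph - khi);
              double* dst = xc + ((size_t)ds * W + ws) * H + (h0 + khi - ph);
              const double* src = ck + ((size_t)d * W + w) * H + h0;
              for (int h = h0; h < h1; ++h) *dst++ += *src++;
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias) {
  int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  int kh = wdim[0], kw = wdim[1], kd = wdim[2], F = wdim[4];
  if (wdim[3] != C) stop("channel mismatch between input and kernel");
  const int K = kh * kw * kd * C, P = H * W * D;
  arma::mat Wm(w.begin(), K, F, false, true);
  NumericVector out(Rcpp::no_init((size_t)P * F * N));
  out.attr("dim") = IntegerVector::create(H, W, D, F, N);
  arma::mat col(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * P * C, H, W, D, C, kh, kw, kd, col);
    arma::mat y(out.begin() + (size_t)n * P * F, P, F, false, true);
    y = col * Wm;
    for (int f = 0; f < F; ++f) y.col(f) += bias[f];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy) {
  int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  int kh = wdim[0], kw = wdim[1], kd = wdim[2], F = wdim[4];
  const int K = kh * kw * kd * C, P = H * W * D;
  arma::mat Wm(w.begin(), K, F, false, true);
  NumericVector gx(Rcpp::no_init((size_t)P * C * N));
  gx.attr("dim") = xdim;
  std::fill(gx.begin(), gx.end(), 0.0);
  arma::mat gW(K, F, arma::fill::zeros);
  arma::vec gB(F, arma::fill::zeros);
  arma::mat col(P, K);
  for (int n = 0; n < N; ++n) {
    arma::mat gyn(const_cast<double*>(gy.begin()) + (size_t)n * P * F,
                  P, F, false, true);
    im2col(x.begin() + (size_t)n * P * C, H, W, D, C, kh, kw, kd, col);
    gW += col.t() * gyn;
    gB += arma::sum(gyn, 0).t();
    arma::mat gcol = gyn * Wm.t();       // P x K
    col2im(gcol, H, W, D, C, kh, kw, kd, gx.begin() + (size_t)n * P * C);
  }
  NumericVector gwR(gW.begin(), gW.end());
  gwR.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gwR,
                      _["gb"] = NumericVector(gB.begin(), gB.end()));
}

// ceiling-mode max pooling: output dims ceil(H/ph) etc., edge windows clipped
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xdim,
                       int ph, int pw, int pd) {
  int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  int OH = (H + ph - 1) / ph, OW = (W + pw - 1) / pw, OD = (D + pd - 1) / pd;
  size_t on = (size_t)OH * OW * OD * C * N;
  NumericVector y(Rcpp::no_init(on));
  IntegerVector idx(Rcpp::no_init(on));
  y.attr("dim") = IntegerVector::create(OH, OW, OD, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)n * C + c) * H * W * D;
      size_t obase = ((size_t)n * C + c) * OH * OW * OD;
      for (int od = 0; od < OD; ++od)
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh) {
            int d1 = std::min((od + 1) * pd, D), w1 = std::min((ow + 1) * pw, W),
                h1 = std::min((oh + 1) * ph, H);
            double best = -std::numeric_limits<double>::infinity();
            size_t bidx = 0;
            for (int d = od * pd; d < d1; ++d)
              for (int w = ow * pw; w < w1; ++w)
                for (int h = oh * ph; h < h1; ++h) {
                  size_t li = base + ((size_t)d * W + w) * H + h;
                  if (xp[li] > best) { best = xp[li]; bidx = li; }
                }
            size_t oo = obase + ((size_t)od * OW + ow) * OH + oh;
            y[oo] = best;
            idx[oo] = (int)bidx;
          }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(IntegerVector idx, NumericVector gy,
                                IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector gx(Rcpp::no_init(nx));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// gradient gate: g * (y > 0), where y is the ReLU output
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector y) {
  NumericVector out(Rcpp::no_init(g.size()));
  out.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < g.size(); ++i) out[i] = y[i] > 0 ? g[i] : 0;
  return out;
}
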