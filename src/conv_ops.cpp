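// Core CPU kernels for the network engine: im2col/col2im convolution
// (forward, input-gradient, weight-gradient) and max pooling.
//
// Tensor layout everywhere: column-major R array (H, W, C, N), so element
// (h, w, c, n) sits at h + H*(w + W*(c + C*n)).  Convolution weights are
// (k, k, Cin/groups, Cout); their column-major flattening of the first three
// dims matches the im2col row order r = kh + k*kw + k*k*cin_local.
//
// Transposed convolution is expressed in R through these same three kernels
// (its forward is conv_bwd_input, etc.), so the package needs no separate
// deconvolution code path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Gather an im2col block for output positions [pos0, pos0+len) of image n,
// channel group g.  Col is (k*k*Cg) x len, zero-filled for padding.
void im2col_block(const double* x, int H, int W, int Cg, int c0,
                  int k, int stride, int pad, int Ho, int Wo,
                  int pos0, int len, arma::mat& Col) {
  const int HW = H * W;
  for (int j = 0; j < len; ++j) {
    const int pos = pos0 + j;
    const int ho = pos % Ho, wo = pos / Ho;
    double* col = Col.colptr(j);
    for (int c = 0; c < Cg; ++c) {
      const double* xc = x + (size_t)(c0 + c) * HW;
      for (int kw = 0; kw < k; ++kw) {
        const int w = wo * stride - pad + kw;
        const bool wok = (w >= 0 && w < W);
        const double* xcol = xc + (size_t)w * H;
        for (int kh = 0; kh < k; ++kh) {
          const int h = ho * stride - pad + kh;
          col[kh + k * kw + k * k * c] =
            (wok && h >= 0 && h < H) ? xcol[h] : 0.0;
        }
      }
    }
  }
}

// Scatter-add a column block back into the image (inverse of im2col_block).
void col2im_block(double* dx, int H, int W, int Cg, int c0,
                  int k, int stride, int pad, int Ho, int Wo,
                  int pos0, int len, const arma::mat& Col) {
  const int HW = H * W;
  for (int j = 0; j < len; ++j) {
    const int pos = pos0 + j;
    const int ho = pos % Ho, wo = pos / Ho;
    const double* col = Col.colptr(j);
    for (int c = 0; c < Cg; ++c) {
      double* xc = dx + (size_t)(c0 + c) * HW;
      for (int kw = 0; kw < k; ++kw) {
        const int w = wo * stride - pad + kw;
        if (w < 0 || w >= W) continue;
        double* xcol = xc + (size_t)w * H;
        for (int kh = 0; kh < k; ++kh) {
          const int h = ho * stride - pad + kh;
          if (h >= 0 && h < H) xcol[h] += col[kh + k * kw + k * k * c];
        }
      }
    }
  }
}

inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Cap im2col buffers at ~64 MB.
inline int chunk_cols(int rows) {
  int n = (int)(8000000 / (size_t)rows);
  return n < 1 ? 1 : n;
}

} // namespace

// x (H,W,Cin,N), w (k,k,Cin/groups,Cout) -> out (Ho,Wo,Cout,N)
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, int k, int cout,
                           int stride, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const int Cg = C / groups, Og = cout / groups;
  const int rows = k * k * Cg, HoWo = Ho * Wo;
  NumericVector out((size_t)HoWo * cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), rows, cout, false, true);
  const int maxlen = std::min(HoWo, chunk_cols(rows));
  arma::mat Col(rows, maxlen);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* on = out.begin() + (size_t)n * HoWo * cout;
    for (int g = 0; g < groups; ++g) {
      const arma::mat Wg = Wm.cols(g * Og, (g + 1) * Og - 1);
      for (int pos0 = 0; pos0 < HoWo; pos0 += maxlen) {
        const int len = std::min(maxlen, HoWo - pos0);
        arma::mat Cb(Col.memptr(), rows, len, false, true);
        im2col_block(xn, H, W, Cg, g * Cg, k, stride, pad, Ho, Wo,
                     pos0, len, Cb);
        arma::mat O = Cb.t() * Wg;  // len x Og
        for (int c = 0; c < Og; ++c)
          std::copy(O.colptr(c), O.colptr(c) + len,
                    on + (size_t)(g * Og + c) * HoWo + pos0);
      }
    }
  }
  return out;
}

// dy (Ho,Wo,Cout,N) -> dx (H,W,Cin,N); H,W given explicitly so the same
// kernel serves as the forward pass of a transposed convolution.
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_input(NumericVector dy, IntegerVector ydim,
                                 NumericVector w, int k, int cin,
                                 int H, int W, int stride, int pad,
                                 int groups) {
  const int Ho = ydim[0], Wo = ydim[1], cout = ydim[2], N = ydim[3];
  const int Cg = cin / groups, Og = cout / groups;
  const int rows = k * k * Cg, HoWo = Ho * Wo;
  NumericVector dx((size_t)H * W * cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, cin, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), rows, cout, false, true);
  const int maxlen = std::min(HoWo, chunk_cols(rows));
  arma::mat DY(maxlen, 1);  // resized per group below
  for (int n = 0; n < N; ++n) {
    const double* yn = dy.begin() + (size_t)n * HoWo * cout;
    double* xn = dx.begin() + (size_t)n * H * W * cin;
    for (int g = 0; g < groups; ++g) {
      const arma::mat Wg = Wm.cols(g * Og, (g + 1) * Og - 1);
      for (int pos0 = 0; pos0 < HoWo; pos0 += maxlen) {
        const int len = std::min(maxlen, HoWo - pos0);
        arma::mat Yb(len, Og);
        for (int c = 0; c < Og; ++c) {
          const double* src = yn + (size_t)(g * Og + c) * HoWo + pos0;
          std::copy(src, src + len, Yb.colptr(c));
        }
        arma::mat Cb = Wg * Yb.t();  // rows x len
        col2im_block(xn, H, W, Cg, g * Cg, k, stride, pad, Ho, Wo,
                     pos0, len, Cb);
      }
    }
  }
  return dx;
}

// x (H,W,Cin,N), dy (Ho,Wo,Cout,N) -> dW (k,k,Cin/groups,Cout), summed over N.
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_weight(NumericVector x, IntegerVector xdim,
                                  NumericVector dy, IntegerVector ydim,
                                  int k, int stride, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = ydim[0], Wo = ydim[1], cout = ydim[2];
  const int Cg = C / groups, Og = cout / groups;
  const int rows = k * k * Cg, HoWo = Ho * Wo;
  NumericVector dw((size_t)rows * cout);
  dw.attr("dim") = IntegerVector::create(k, k, Cg, cout);
  arma::mat DW(dw.begin(), rows, cout, false, true);
  const int maxlen = std::min(HoWo, chunk_cols(rows));
  arma::mat Col(rows, maxlen);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* yn = dy.begin() + (size_t)n * HoWo * cout;
    for (int g = 0; g < groups; ++g) {
      for (int pos0 = 0; pos0 < HoWo; pos0 += maxlen) {
        const int len = std::min(maxlen, HoWo - pos0);
        arma::mat Cb(Col.memptr(), rows, len, false, true);
        im2col_block(xn, H, W, Cg, g * Cg, k, stride, pad, Ho, Wo,
                     pos0, len, Cb);
        arma::mat Yb(len, Og);
        for (int c = 0; c < Og; ++c) {
          const double* src = yn + (size_t)(g * Og + c) * HoWo + pos0;
          std::copy(src, src + len, Yb.colptr(c));
        }
        DW.cols(g * Og, (g + 1) * Og - 1) += Cb * Yb;
      }
    }
  }
  return dw;
}

// Max pooling with argmax bookkeeping (1-based linear indices into x) so the
// backward pass is a pure scatter.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim,
                     int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx((size_t)Ho * Wo * C * N);  // double to allow >2^31 inputs
  double* op = out.begin();
  double* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const double* xc = x.begin() + base;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; size_t bi = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              const double v = xc[h + (size_t)w * H];
              if (v > best) { best = v; bi = base + h + (size_t)w * H; }
            }
          }
          // (ho, wo) fastest within channel c: match (Ho,Wo,C,N) layout
          const size_t oo = ((size_t)n * C + c) * Ho * Wo + ho + (size_t)wo * Ho;
          op[oo] = best;
          ip[oo] = (double)(bi + 1);
          (void)o;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, NumericVector idx,
                              double xlen, IntegerVector xdim) {
  NumericVector dx((size_t)xlen);
  dx.attr("dim") = xdim;
  const double* dp = dy.begin();
  const double* ip = idx.begin();
  double* xp = dx.begin();
  const size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) xp[(size_t)(ip[i] - 1.0)] += dp[i];
  return dx;
}
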