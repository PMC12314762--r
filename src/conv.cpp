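// Convolution forward/backward kernels for the fully convolutional backbone.
// Layout: activations are H x W x C x N arrays (R column-major); kernels are
// k x k x Cin x Cout.  im2col rows are ordered (dh fastest, then dw, then c),
// matching the flattening of the kernel array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// Gather one sample into the im2col matrix: (Ho*Wo) x (k*k*C).
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * (dw + k * c);
        double* Mcol = M.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + dw - pad;
          bool w_ok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + dh - pad;
            double v = 0.0;
            if (w_ok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wi];
            Mcol[ho + (size_t)Ho * wo] = v;
          }
        }
      }
    }
  }
}

// Scatter-add the im2col matrix back onto the input grid (transpose of im2col).
static void col2im(const arma::mat& M, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * (dw + k * c);
        const double* Mcol = M.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + dw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + dh - pad;
            if (hi < 0 || hi >= H) continue;
            gc[hi + (size_t)H * wi] += Mcol[ho + (size_t)Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  int dx[4], dw[4];
  get_dims4(x, dx);
  get_dims4(w, dw);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], K = dw[3];
  if (dw[1] != k) stop("kernel must be square");
  if (dw[2] != C) stop("kernel input channels do not match input");
  if (b.size() != K) stop("bias length must equal output channels");
  if (stride < 1) stop("stride must be >= 1");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  NumericVector y((size_t)Ho * Wo * K * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, K, N);

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, K, false, true);
  arma::mat M((size_t)Ho * Wo, (size_t)k * k * C);
  arma::rowvec bv(const_cast<double*>(b.begin()), K, false, true);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    im2col(xn, H, W, C, k, stride, pad, Ho, Wo, M);
    arma::mat Yn(y.begin() + (size_t)Ho * Wo * K * n, (size_t)Ho * Wo, K, false, true);
    Yn = M * Wm;
    Yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                     int stride, int pad) {
  int dx[4], dw[4], dg[4];
  get_dims4(x, dx);
  get_dims4(w, dw);
  get_dims4(gy, dg);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], K = dw[3];
  int Ho = dg[0], Wo = dg[1];
  if (dg[2] != K || dg[3] != N) stop("gradient dims do not match");

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((size_t)k * k * C * K);
  gw.attr("dim") = IntegerVector::create(k, k, C, K);
  NumericVector gb(K);

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, K, false, true);
  arma::mat Gw(gw.begin(), (size_t)k * k * C, K, false, true);
  arma::mat M((size_t)Ho * Wo, (size_t)k * k * C);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * K * n,
                 (size_t)Ho * Wo, K, false, true);
    im2col(xn, H, W, C, k, stride, pad, Ho, Wo, M);
    Gw += M.t() * Gy;
    for (int kk = 0; kk < K; ++kk) gb[kk] += arma::accu(Gy.col(kk));
    arma::mat Gcol = Gy * Wm.t();  // (Ho*Wo) x (k*k*C)
    col2im(Gcol, H, W, C, k, stride, pad, Ho, Wo,
           gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
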