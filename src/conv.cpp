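// Minimal convolution / pooling kernels for the image branch.
// Layout convention: feature tensors are R arrays dim c(H, W, C, N)
// (column-major), weights dim c(kh, kw, Cin, Cout). The whole batch is
// lowered into one im2col matrix (N*Ho*Wo rows) so each layer costs a
// single BLAS gemm per direction.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Replicate (clamp) padding: out-of-range taps read the nearest edge
// pixel. Zero padding depresses border activations, which corrupts the
// mean-threshold SCDA masks; clamping keeps the tap map border-neutral.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// fill rows [n*Ho*Wo, (n+1)*Ho*Wo) of the batch im2col matrix for image n
static void im2col_block(const double* x, int H, int W, int C, long n_off,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo, arma::mat& col, long row0) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int cc = i + kh * (j + kw * c);
        double* dst = col.colptr(cc) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = clampi(wo * stride - pad + j, 0, W - 1);
          const double* src = x + n_off + (long)H * (wi + (long)W * c);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = clampi(ho * stride - pad + i, 0, H - 1);
            dst[ho + Ho * wo] = src[hi];
          }
        }
      }
    }
  }
}

static void col2im_block(double* dx, int H, int W, int C, long n_off,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo, const arma::mat& col, long row0) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int cc = i + kh * (j + kw * c);
        const double* src = col.colptr(cc) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = clampi(wo * stride - pad + j, 0, W - 1);
          double* dst = dx + n_off + (long)H * (wi + (long)W * c);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = clampi(ho * stride - pad + i, 0, H - 1);
            dst[hi] += src[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], K = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  long hw = (long)Ho * Wo;
  NumericVector y(hw * K * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, K, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, K, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), K, false, true);
  arma::mat col(hw * N, kh * kw * C);
  long xstep = (long)H * W * C;
  for (int n = 0; n < N; ++n)
    im2col_block(x.begin(), H, W, C, n * xstep, kh, kw, stride, pad,
                 Ho, Wo, col, n * hw);
  arma::mat out = col * Wm;              // (N*Ho*Wo) x K
  out.each_row() += bv;
  // out column k, row block n  ->  y[ , , k, n]
  for (int k = 0; k < K; ++k) {
    const double* src = out.colptr(k);
    for (int n = 0; n < N; ++n)
      std::copy(src + n * hw, src + (n + 1) * hw,
                y.begin() + ((long)n * K + k) * hw);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], K = wd[3];
  int Ho = yd[0], Wo = yd[1];
  long hw = (long)Ho * Wo;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(K);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, K, false, true);
  long xstep = (long)H * W * C;
  arma::mat col(hw * N, kh * kw * C);
  for (int n = 0; n < N; ++n)
    im2col_block(x.begin(), H, W, C, n * xstep, kh, kw, stride, pad,
                 Ho, Wo, col, n * hw);
  // regroup dy into (N*Ho*Wo) x K
  arma::mat dY(hw * N, K);
  for (int k = 0; k < K; ++k) {
    double* dst = dY.colptr(k);
    for (int n = 0; n < N; ++n)
      std::copy(dy.begin() + ((long)n * K + k) * hw,
                dy.begin() + ((long)n * K + k + 1) * hw, dst + n * hw);
  }
  arma::mat dWm(dw.begin(), kh * kw * C, K, false, true);
  dWm = col.t() * dY;
  arma::rowvec dbv = arma::sum(dY, 0);
  std::copy(dbv.begin(), dbv.end(), db.begin());
  arma::mat dcol = dY * Wm.t();
  for (int n = 0; n < N; ++n)
    col2im_block(dx.begin(), H, W, C, n * xstep, kh, kw, stride, pad,
                 Ho, Wo, dcol, n * hw);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled tensor and argmax indices
// (1-based linear index into the input array) for the backward pass.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((long)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  long pos = 0;
  long planes = (long)C * N;
  for (long p = 0; p < planes; ++p) {
    long base_p = p * (long)H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      long base = base_p + (long)H * (2 * wo);
      for (int ho = 0; ho < Ho; ++ho) {
        long i0 = base + 2 * ho;
        long cand[4] = { i0, i0 + 1, i0 + H, i0 + H + 1 };
        long best = cand[0];
        for (int t = 1; t < 4; ++t) if (xp[cand[t]] > xp[best]) best = cand[t];
        y[pos] = xp[best];
        idx[pos] = (int)(best + 1);
        ++pos;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector xdim) {
  long n = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (long i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}
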