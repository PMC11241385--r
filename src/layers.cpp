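// Hot loops of the convolutional network: im2col/col2im-based convolution
// and 2x2 stride-2 max pooling. Arrays use the internal (C, H, W, B)
// column-major layout; column ordering of the unrolled patch matrix is
// channel fastest, then kernel row, then kernel column, and output pixels
// run row fastest, then column, then batch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_(const double* x, int C, int H, int W, int B,
                         int k, int pad) {
  const size_t HW = (size_t)H * W;
  arma::mat cols(C * k * k, HW * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (size_t)C * HW * b;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* dst = cols.colptr(HW * b + (size_t)H * w + h);
        for (int kw = 0; kw < k; ++kw) {
          const int ww = w + kw - pad;
          if (ww < 0 || ww >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hh = h + kh - pad;
            if (hh < 0 || hh >= H) continue;
            const double* src = xb + (size_t)C * (hh + (size_t)H * ww);
            double* d = dst + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) d[c] = src[c];
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add inverse of im2col_, used for the input gradient
static void col2im_(const arma::mat& cols, double* x, int C, int H, int W,
                    int B, int k, int pad) {
  const size_t HW = (size_t)H * W;
  std::fill(x, x + (size_t)C * HW * B, 0.0);
  for (int b = 0; b < B; ++b) {
    double* xb = x + (size_t)C * HW * b;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* src = cols.colptr(HW * b + (size_t)H * w + h);
        for (int kw = 0; kw < k; ++kw) {
          const int ww = w + kw - pad;
          if (ww < 0 || ww >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hh = h + kh - pad;
            if (hh < 0 || hh >= H) continue;
            double* d = xb + (size_t)C * (hh + (size_t)H * ww);
            const double* s = src + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
}

// Same-padded stride-1 convolution (cross-correlation) forward pass.
// x: (C,H,W,B); Wm: (Cout x C*k*k); returns y (Cout,H,W,B) and the
// unrolled patch matrix for reuse in the backward pass.
// [[Rcpp::export(name = ".convForwardC")]]
List convForwardC(NumericVector x, NumericMatrix Wm, NumericVector bias,
                  IntegerVector dims, int k, int pad) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Cout = Wm.nrow();
  arma::mat cols = im2col_(x.begin(), C, H, W, B, k, pad);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::vec ba(bias.begin(), Cout);
  arma::mat y = Wa * cols;
  y.each_col() += ba;
  NumericVector yv(y.begin(), y.end());
  yv.attr("dim") = IntegerVector::create(Cout, H, W, B);
  return List::create(_["y"] = yv, _["cols"] = cols);
}

// Backward pass: gradients w.r.t. input, weights and bias.
// [[Rcpp::export(name = ".convBackwardC")]]
List convBackwardC(NumericVector dy, NumericMatrix cols, NumericMatrix Wm,
                   IntegerVector dims, int k, int pad) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Cout = Wm.nrow();
  const size_t n = (size_t)H * W * B;
  arma::mat dym(dy.begin(), Cout, n, false);
  arma::mat colsA(cols.begin(), cols.nrow(), cols.ncol(), false);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat dW = dym * colsA.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dcols = Wa.t() * dym;
  NumericVector dx((size_t)C * H * W * B);
  col2im_(dcols, dx.begin(), C, H, W, B, k, pad);
  dx.attr("dim") = IntegerVector::create(C, H, W, B);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 stride-2 max pooling with floor division of odd extents (the final
// row/column of an odd input is dropped). `which` records the argmax
// position 0..3 in (dh, dw) scan order, ties to the first maximum.
// [[Rcpp::export(name = ".poolForwardC")]]
List poolForwardC(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)C * Ho * Wo * B);
  IntegerVector wh((size_t)C * Ho * Wo * B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* wp = wh.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (size_t)C * H * W * b;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t oi = (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          double best = -HUGE_VAL;
          int arg = 0, pos = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              const double v =
                  xb[c + (size_t)C * ((2 * ho + dh) + (size_t)H * (2 * wo + dw))];
              if (v > best) { best = v; arg = pos; }
              ++pos;
            }
          }
          yp[oi + c] = best;
          wp[oi + c] = arg;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  wh.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  return List::create(_["y"] = y, _["which"] = wh);
}

// [[Rcpp::export(name = ".poolBackwardC")]]
NumericVector poolBackwardC(NumericVector dy, IntegerVector wh,
                            IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)C * H * W * B);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* wp = wh.begin();
  for (int b = 0; b < B; ++b) {
    double* xb = dxp + (size_t)C * H * W * b;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t oi = (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * b));
        for (int c = 0; c < C; ++c) {
          const int arg = wp[oi + c];
          const int dh = arg % 2, dw = arg / 2;
          xb[c + (size_t)C * ((2 * ho + dh) + (size_t)H * (2 * wo + dw))] +=
              dyp[oi + c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, B);
  return dx;
}
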