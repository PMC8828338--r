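#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Literal d-dilated convolution (f *_d r)(p) = sum_{s + d t = p} f(s) r(t)
// over the kernel support [-k, k]^2, zero padding, "same" output size.
// [[Rcpp::export]]
arma::mat dilated_conv2d_cpp(const arma::mat& f, const arma::mat& r, const int d) {
  const int H = f.n_rows, W = f.n_cols;
  const int kh = r.n_rows, kw = r.n_cols;
  const int k1 = (kh - 1) / 2, k2 = (kw - 1) / 2;
  arma::mat out(H, W, arma::fill::zeros);
  for (int p2 = 0; p2 < W; ++p2) {
    for (int p1 = 0; p1 < H; ++p1) {
      double acc = 0.0;
      for (int t2 = -k2; t2 <= k2; ++t2) {
        const int s2 = p2 - d * t2;
        if (s2 < 0 || s2 >= W) continue;
        for (int t1 = -k1; t1 <= k1; ++t1) {
          const int s1 = p1 - d * t1;
          if (s1 < 0 || s1 >= H) continue;
          acc += f(s1, s2) * r(t1 + k1, t2 + k2);
        }
      }
      out(p1, p2) = acc;
    }
  }
  return out;
}

// Batched 2D cross-correlation layer used inside the network.
// X: (H, W, B, Ci) array, Wt: (kh, kw, Ci, Co), bias: length Co.
// "Same" zero padding; dilation d. Output (H, W, B, Co).
// Row-blocked im2col + GEMM keeps peak memory bounded for large slices.

static inline void fill_col_block(const double* xp, arma::mat& col,
                                  int H, int W, int B, int Ci,
                                  int kh, int kw, int d,
                                  int b, int h0, int hb) {
  const int k1 = (kh - 1) / 2, k2 = (kw - 1) / 2;
  col.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * (j + kw * ci);
        double* cq = col.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int sw = w + d * (j - k2);
          if (sw < 0 || sw >= W) continue;
          const double* xcol =
            xp + ((size_t)ci * B + b) * (size_t)W * H + (size_t)sw * H;
          double* cdst = cq + (size_t)hb * w;
          for (int hh = 0; hh < hb; ++hh) {
            const int sh = (h0 + hh) + d * (i - k1);
            if (sh < 0 || sh >= H) continue;
            cdst[hh] = xcol[sh];
          }
        }
      }
    }
  }
}

static int row_block_size(int W, int K) {
  double target = 2e7 / ((double)W * (double)K);
  int rb = (int)target;
  if (rb < 1) rb = 1;
  return rb;
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(const NumericVector& X, const NumericVector& Wt,
                           const NumericVector& bias, const int d) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], Ci = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != Ci) stop("kernel input channels (%d) do not match input (%d)", (int)wd[2], Ci);
  if (d < 1) stop("dilation must be >= 1");
  const int K = kh * kw * Ci;
  const arma::mat Wmat(const_cast<double*>(Wt.begin()), K, Co, false, true);

  NumericVector Y((R_xlen_t)H * W * B * Co);
  Y.attr("dim") = IntegerVector::create(H, W, B, Co);
  const double* xp = X.begin();
  double* yp = Y.begin();
  const int rb = row_block_size(W, K);

  for (int b = 0; b < B; ++b) {
    for (int h0 = 0; h0 < H; h0 += rb) {
      const int hb = std::min(rb, H - h0);
      arma::mat col(hb * W, K);
      fill_col_block(xp, col, H, W, B, Ci, kh, kw, d, b, h0, hb);
      arma::mat Yb = col * Wmat;
      for (int co = 0; co < Co; ++co) {
        const double bs = bias[co];
        const double* ybc = Yb.colptr(co);
        double* ycol = yp + ((size_t)co * B + b) * (size_t)W * H;
        for (int w = 0; w < W; ++w) {
          double* ydst = ycol + (size_t)w * H + h0;
          const double* ysrc = ybc + (size_t)hb * w;
          for (int hh = 0; hh < hb; ++hh) ydst[hh] = ysrc[hh] + bs;
        }
      }
    }
  }
  return Y;
}

// Gradients of the cross-correlation layer.
// Returns list(dX, dW, db) for upstream gradient dY of shape (H, W, B, Co).
// [[Rcpp::export]]
List conv_bwd_cpp(const NumericVector& X, const NumericVector& Wt,
                  const NumericVector& dY, const int d) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], Ci = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int k1 = (kh - 1) / 2, k2 = (kw - 1) / 2;
  const int K = kh * kw * Ci;
  const arma::mat Wmat(const_cast<double*>(Wt.begin()), K, Co, false, true);

  NumericVector dX((R_xlen_t)H * W * B * Ci);
  dX.attr("dim") = IntegerVector::create(H, W, B, Ci);
  NumericVector dWout((R_xlen_t)kh * kw * Ci * Co);
  dWout.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  NumericVector db(Co);

  arma::mat dWacc(K, Co, arma::fill::zeros);
  arma::vec dbacc(Co, arma::fill::zeros);
  const double* xp = X.begin();
  const double* gp = dY.begin();
  double* dxp = dX.begin();
  const int rb = row_block_size(W, K);

  for (int b = 0; b < B; ++b) {
    for (int h0 = 0; h0 < H; h0 += rb) {
      const int hb = std::min(rb, H - h0);
      arma::mat col(hb * W, K);
      fill_col_block(xp, col, H, W, B, Ci, kh, kw, d, b, h0, hb);
      arma::mat dYb(hb * W, Co);
      for (int co = 0; co < Co; ++co) {
        const double* gcol = gp + ((size_t)co * B + b) * (size_t)W * H;
        double* dst = dYb.colptr(co);
        for (int w = 0; w < W; ++w) {
          const double* gsrc = gcol + (size_t)w * H + h0;
          double* d2 = dst + (size_t)hb * w;
          for (int hh = 0; hh < hb; ++hh) d2[hh] = gsrc[hh];
        }
        dbacc[co] += arma::accu(dYb.col(co));
      }
      dWacc += col.t() * dYb;
      arma::mat M = dYb * Wmat.t();  // (hb*W) x K, scatter-add into dX
      for (int ci = 0; ci < Ci; ++ci) {
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            const int q = i + kh * (j + kw * ci);
            const double* mq = M.colptr(q);
            for (int w = 0; w < W; ++w) {
              const int sw = w + d * (j - k2);
              if (sw < 0 || sw >= W) continue;
              double* xcol =
                dxp + ((size_t)ci * B + b) * (size_t)W * H + (size_t)sw * H;
              const double* msrc = mq + (size_t)hb * w;
              for (int hh = 0; hh < hb; ++hh) {
                const int sh = (h0 + hh) + d * (i - k1);
                if (sh < 0 || sh >= H) continue;
                xcol[sh] += msrc[hh];
              }
            }
          }
        }
      }
    }
  }
  std::copy(dWacc.begin(), dWacc.end(), dWout.begin());
  for (int co = 0; co < Co; ++co) db[co] = dbacc[co];
  return List::create(_["dX"] = dX, _["dW"] = dWout, _["db"] = db);
}
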