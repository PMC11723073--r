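#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Activations are column-major arrays with dim (H, W, C, N). The
// convolution is evaluated as im2col followed by one BLAS GEMM, entirely in
// C++ so no intermediate patch matrices or permuted copies surface in R.
// Patch-matrix layout:
//   rows:    oh + outH*ow + outH*outW*n      (output pixel, batch element)
//   columns: ki + kh*kj + kh*kw*c            (kernel tap, input channel)

static void im2col_fill(const double* xp, arma::mat& cols,
                        int H, int W, int C, int N,
                        int kh, int kw, int stride, int pad,
                        int outH, int outW) {
  const int nrow = outH * outW * N;
  double* op = cols.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* ocol = op + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xplane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
          for (int ow = 0; ow < outW; ++ow) {
            const int sw = ow * stride - pad + kj;
            double* orow = ocol + outH * (ow + outW * n);
            if (sw < 0 || sw >= W) {
              std::fill(orow, orow + outH, 0.0);
              continue;
            }
            const double* xcolm = xplane + (R_xlen_t)sw * H;
            for (int oh = 0; oh < outH; ++oh) {
              const int sh = oh * stride - pad + ki;
              orow[oh] = (sh < 0 || sh >= H) ? 0.0 : xcolm[sh];
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col_fill: scatter-add patch gradients back onto the grid.
static void col2im_add(const arma::mat& cols, double* xp,
                       int H, int W, int C, int N,
                       int kh, int kw, int stride, int pad,
                       int outH, int outW) {
  const int nrow = outH * outW * N;
  const double* cp = cols.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double* ccol = cp + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          double* xplane = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
          for (int ow = 0; ow < outW; ++ow) {
            const int sw = ow * stride - pad + kj;
            if (sw < 0 || sw >= W) continue;
            const double* crow = ccol + outH * (ow + outW * n);
            double* xcolm = xplane + (R_xlen_t)sw * H;
            for (int oh = 0; oh < outH; ++oh) {
              const int sh = oh * stride - pad + ki;
              if (sh >= 0 && sh < H) xcolm[sh] += crow[oh];
            }
          }
        }
      }
    }
  }
}

// out(oh, ow, co, n) <- om(oh + outH*(ow + outW*n), co) [+ b(co)]
static void gemmout_to_array(const arma::mat& om, double* out,
                             int outH, int outW, int K, int N,
                             const double* b) {
  const int nrow = outH * outW * N;
  const int plane = outH * outW;
  for (int co = 0; co < K; ++co) {
    const double* oc = om.memptr() + (R_xlen_t)co * nrow;
    const double bc = b ? b[co] : 0.0;
    for (int n = 0; n < N; ++n) {
      double* dst = out + ((R_xlen_t)co + (R_xlen_t)K * n) * plane;
      const double* src = oc + (R_xlen_t)n * plane;
      for (int p = 0; p < plane; ++p) dst[p] = src[p] + bc;
    }
  }
}

// dm(oh + outH*(ow + outW*n), co) <- dout(oh, ow, co, n)
static void array_to_gemmout(const double* dout, arma::mat& dm,
                             int outH, int outW, int K, int N) {
  const int nrow = outH * outW * N;
  const int plane = outH * outW;
  for (int co = 0; co < K; ++co) {
    double* dc = dm.memptr() + (R_xlen_t)co * nrow;
    for (int n = 0; n < N; ++n) {
      const double* src = dout + ((R_xlen_t)co + (R_xlen_t)K * n) * plane;
      double* dst = dc + (R_xlen_t)n * plane;
      std::copy(src, src + plane, dst);
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_fw_rcpp(NumericVector x, NumericVector W,
                           Nullable<NumericVector> b,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int outH = (H + 2 * pad - kh) / stride + 1;
  const int outW = (Wd + 2 * pad - kw) / stride + 1;
  arma::mat cols((R_xlen_t)outH * outW * N, (R_xlen_t)kh * kw * C);
  im2col_fill(x.begin(), cols, H, Wd, C, N, kh, kw, stride, pad, outH, outW);
  const arma::mat Wm(const_cast<double*>(W.begin()),
                     (R_xlen_t)kh * kw * C, K, false, true);
  arma::mat om = cols * Wm;
  NumericVector out((R_xlen_t)outH * outW * K * N);
  gemmout_to_array(om, out.begin(), outH, outW, K, N,
                   b.isNotNull() ? NumericVector(b).begin() : nullptr);
  out.attr("dim") = IntegerVector::create(outH, outW, K, N);
  return out;
}

// Reverse pass: gradients w.r.t. the input and/or the parameters. `x_w`
// substitutes the activations used for the weight gradient (the tangent
// activations in the gradient-penalty double-backward pass, where the bias
// gradient is structurally zero).
// [[Rcpp::export]]
List conv_bw_rcpp(NumericVector x, NumericVector W, NumericVector dout,
                  int stride, int pad, bool need_dx, bool need_dw,
                  bool bias_grad, Nullable<NumericVector> x_w) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int outH = (H + 2 * pad - kh) / stride + 1;
  const int outW = (Wd + 2 * pad - kw) / stride + 1;
  const R_xlen_t nrow = (R_xlen_t)outH * outW * N;
  const R_xlen_t ncol = (R_xlen_t)kh * kw * C;

  arma::mat dm(nrow, K);
  array_to_gemmout(dout.begin(), dm, outH, outW, K, N);
  const arma::mat Wm(const_cast<double*>(W.begin()), ncol, K, false, true);

  List res;
  if (need_dw) {
    arma::mat cols(nrow, ncol);
    const double* src = x_w.isNotNull() ? NumericVector(x_w).begin()
                                        : x.begin();
    im2col_fill(src, cols, H, Wd, C, N, kh, kw, stride, pad, outH, outW);
    arma::mat dWm = cols.t() * dm;
    NumericVector dW(dWm.begin(), dWm.end());
    dW.attr("dim") = wd;
    NumericVector db(K);
    if (bias_grad) {
      arma::rowvec s = arma::sum(dm, 0);
      std::copy(s.begin(), s.end(), db.begin());
    }
    res["dW"] = dW;
    res["db"] = db;
  }
  if (need_dx) {
    arma::mat dcols = dm * Wm.t();
    NumericVector dx((R_xlen_t)H * Wd * C * N);
    col2im_add(dcols, dx.begin(), H, Wd, C, N, kh, kw, stride, pad,
               outH, outW);
    dx.attr("dim") = IntegerVector::create(H, Wd, C, N);
    res["dx"] = dx;
  }
  return res;
}

// Channel-wise concatenation of two (H, W, C, N) batches.
// [[Rcpp::export]]
NumericVector concat_ch_rcpp(NumericVector a, NumericVector b) {
  IntegerVector ad = a.attr("dim"), bd = b.attr("dim");
  const int H = ad[0], W = ad[1], Ca = ad[2], N = ad[3], Cb = bd[2];
  const R_xlen_t plane = (R_xlen_t)H * W;
  NumericVector out(plane * (Ca + Cb) * N);
  double* op = out.begin();
  const double* ap = a.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n) {
    std::copy(ap + plane * Ca * n, ap + plane * Ca * (n + 1),
              op + plane * (Ca + Cb) * n);
    std::copy(bp + plane * Cb * n, bp + plane * Cb * (n + 1),
              op + plane * ((Ca + Cb) * n + Ca));
  }
  out.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  return out;
}

// Separable resampling of every (channel, batch) plane:
// y[,,c,n] = Mh %*% x[,,c,n] %*% t(Mw). Used by the generator's decoder
// upsampling layers and their adjoint (pass transposed matrices).
// [[Rcpp::export]]
NumericVector upsample_rcpp(NumericVector x, NumericMatrix Mh,
                            NumericMatrix Mw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = Mh.nrow(), W2 = Mw.nrow();
  const arma::mat Mh_(Mh.begin(), H2, H, false, true);
  const arma::mat Mw_(Mw.begin(), W2, W, false, true);
  NumericVector out((R_xlen_t)H2 * W2 * C * N);
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int p = 0; p < C * N; ++p) {
    const arma::mat X(const_cast<double*>(xp) + (R_xlen_t)p * H * W,
                      H, W, false, true);
    arma::mat Y(op + (R_xlen_t)p * H2 * W2, H2, W2, false, true);
    Y = Mh_ * X * Mw_.t();
  }
  return out;
}
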