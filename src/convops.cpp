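// Low-level image/tensor kernels: im2col, col2im, 2-D convolution
// forward/backward and max-pooling. Tensors are R arrays in (H, W, C, N)
// order; filters are (kh, kw, Cin, Cout). All loops are column-major so the
// flattened filter array maps directly onto the im2col row order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int k, int stride, int pad, int dil) {
  int eff = (k - 1) * dil + 1;
  return (H + 2 * pad - eff) / stride + 1;
}

// Fill the im2col matrix for one (H, W, C) slab. Rows are indexed
// i + kh*(j + kw*c) which equals the column-major flattening of a
// (kh, kw, C) filter; columns are output locations ho + Ho*wo.
static void im2col_fill(const double* x, int H, int W, int C,
                        int kh, int kw, int stride, int pad, int dil,
                        arma::mat& cols) {
  int Ho = out_dim(H, kh, stride, pad, dil);
  int Wo = out_dim(W, kw, stride, pad, dil);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int wi = wo * stride - pad + j * dil;
          for (int i = 0; i < kh; ++i) {
            int hi = ho * stride - pad + i * dil;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = xc[hi + (size_t)H * wi];
            dst[i + kh * (j + kw * c)] = v;
          }
        }
      }
    }
  }
}

// Adjoint of im2col_fill: accumulate columns back into the (H, W, C) slab.
static void col2im_acc(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int dil,
                       double* x) {
  int Ho = out_dim(H, kh, stride, pad, dil);
  int Wo = out_dim(W, kw, stride, pad, dil);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* xc = x + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int wi = wo * stride - pad + j * dil;
          for (int i = 0; i < kh; ++i) {
            int hi = ho * stride - pad + i * dil;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              xc[hi + (size_t)H * wi] += src[i + kh * (j + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims,
                         int kh, int kw, int stride, int pad, int dil) {
  int H = dims[0], W = dims[1], C = dims[2];
  int Ho = out_dim(H, kh, stride, pad, dil);
  int Wo = out_dim(W, kw, stride, pad, dil);
  arma::mat cols(kh * kw * C, Ho * Wo);
  im2col_fill(REAL(x), H, W, C, kh, kw, stride, pad, dil, cols);
  return wrap(cols);
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector dims,
                         int kh, int kw, int stride, int pad, int dil) {
  int H = dims[0], W = dims[1], C = dims[2];
  NumericVector out(H * W * C);
  arma::mat cm(cols.begin(), cols.nrow(), cols.ncol(), false);
  col2im_acc(cm, H, W, C, kh, kw, stride, pad, dil, REAL(out));
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdims,
                             NumericVector w, IntegerVector wdims,
                             NumericVector bias,
                             int stride, int pad, int dil) {
  int H = xdims[0], W = xdims[1], C = xdims[2], N = xdims[3];
  int kh = wdims[0], kw = wdims[1], Co = wdims[3];
  int Ho = out_dim(H, kh, stride, pad, dil);
  int Wo = out_dim(W, kw, stride, pad, dil);
  arma::mat Wm(REAL(w), kh * kw * C, Co, false);   // (kh*kw*Cin) x Cout
  arma::vec b(REAL(bias), Co, false);
  NumericVector y((size_t)Ho * Wo * Co * N);
  arma::mat cols(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_fill(REAL(x) + (size_t)H * W * C * n, H, W, C,
                kh, kw, stride, pad, dil, cols);
    arma::mat yn = cols.t() * Wm;                   // L x Cout
    yn.each_row() += b.t();
    std::copy(yn.begin(), yn.end(), REAL(y) + (size_t)Ho * Wo * Co * n);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdims,
                    NumericVector w, IntegerVector wdims,
                    NumericVector dy,
                    int stride, int pad, int dil) {
  int H = xdims[0], W = xdims[1], C = xdims[2], N = xdims[3];
  int kh = wdims[0], kw = wdims[1], Co = wdims[3];
  int Ho = out_dim(H, kh, stride, pad, dil);
  int Wo = out_dim(W, kw, stride, pad, dil);
  int L = Ho * Wo;
  arma::mat Wm(REAL(w), kh * kw * C, Co, false);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat dW(kh * kw * C, Co, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  arma::mat cols(kh * kw * C, L);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(REAL(dy) + (size_t)L * Co * n, L, Co, false); // L x Cout
    im2col_fill(REAL(x) + (size_t)H * W * C * n, H, W, C,
                kh, kw, stride, pad, dil, cols);
    dW += cols * dyn;
    db += arma::sum(dyn, 0).t();
    arma::mat dcols = Wm * dyn.t();                 // rows x L
    col2im_acc(dcols, H, W, C, kh, kw, stride, pad, dil,
               REAL(dx) + (size_t)H * W * C * n);
  }
  dx.attr("dim") = xdims;
  NumericVector dWr(wrap(dW));
  dWr.attr("dim") = wdims;
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = wrap(db));
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdims,
                     int k, int stride, int pad) {
  int H = xdims[0], W = xdims[1], C = xdims[2], N = xdims[3];
  int Ho = out_dim(H, k, stride, pad, 1);
  int Wo = out_dim(W, k, stride, pad, 1);
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);      // 0-based flat index into x
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      size_t yoff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xp[xoff + hi + (size_t)H * wi];
              if (v > best) { best = v; besti = (int)(xoff + hi + (size_t)H * wi); }
            }
          }
          if (besti < 0) { best = 0.0; besti = 0; }  // fully padded window
          yp[yoff + ho + (size_t)Ho * wo] = best;
          ap[yoff + ho + (size_t)Ho * wo] = besti;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector argmax,
                              IntegerVector xdims) {
  NumericVector dx((size_t)xdims[0] * xdims[1] * xdims[2] * xdims[3]);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ap = INTEGER(argmax);
  R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dxp[ap[i]] += dyp[i];
  dx.attr("dim") = xdims;
  return dx;
}
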