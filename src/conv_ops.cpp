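// Convolution kernels for the segmentation network.
//
// Feature maps are stored channel-first as R arrays with dim (C, H, W, N),
// i.e. the channel index varies fastest in memory.  Convolution weights are
// (C_out, C_in*k*k) matrices whose column index encodes (c_in, dh, dw) as
// c + C_in*(dh + k*dw); transposed-convolution weights are
// (C_in, C_out*k*k) with the analogous encoding on the output side.
// im2col/col2im use the same encoding, so both directions reduce to one
// dense matrix product per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather (C,H,W) image-side buffer into a (C*k*k, Ho*Wo) patch matrix.
static void im2col_one(const double* x, int C, int H, int W,
                       int k, int stride, int pad, arma::mat& cols) {
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  cols.zeros(C * k * k, Ho * Wo);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      double* col = cols.colptr(oh + Ho * ow);
      for (int dw = 0; dw < k; ++dw) {
        const int iw = ow * stride - pad + dw;
        if (iw < 0 || iw >= W) continue;
        for (int dh = 0; dh < k; ++dh) {
          const int ih = oh * stride - pad + dh;
          if (ih < 0 || ih >= H) continue;
          const double* src = x + (size_t)C * (ih + (size_t)H * iw);
          double* dst = col + C * (dh + k * dw);
          std::copy(src, src + C, dst);
        }
      }
    }
  }
}

// Adjoint of im2col_one: scatter-add patches back into the image buffer.
static void col2im_one(const arma::mat& cols, double* x, int C, int H, int W,
                       int k, int stride, int pad) {
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const double* col = cols.colptr(oh + Ho * ow);
      for (int dw = 0; dw < k; ++dw) {
        const int iw = ow * stride - pad + dw;
        if (iw < 0 || iw >= W) continue;
        for (int dh = 0; dh < k; ++dh) {
          const int ih = oh * stride - pad + dh;
          if (ih < 0 || ih >= H) continue;
          double* dst = x + (size_t)C * (ih + (size_t)H * iw);
          const double* src = col + C * (dh + k * dw);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("expected a (C, H, W, N) array");
  return d;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                         int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  const arma::vec bv(b.begin(), b.size(), false);
  const int Cout = Wm.n_rows;
  if ((int)Wm.n_cols != C * k * k) stop("weight/input channel mismatch");
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  NumericVector y(Cout * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)C * H * W * n, C, H, W, k, stride, pad, cols);
    arma::mat Y(y.begin() + (size_t)Cout * Ho * Wo * n, Cout, Ho * Wo, false, true);
    Y = Wm * cols;
    Y.each_col() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  const int Cout = Wm.n_rows;
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  arma::mat dW(Cout, C * k * k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)C * H * W * n, C, H, W, k, stride, pad, cols);
    const arma::mat DY(const_cast<double*>(dy.begin()) + (size_t)Cout * Ho * Wo * n,
                       Cout, Ho * Wo, false, true);
    dW += DY * cols.t();
    db += arma::sum(DY, 1);
    arma::mat dcols = Wm.t() * DY;
    col2im_one(dcols, dx.begin() + (size_t)C * H * W * n, C, H, W, k, stride, pad);
  }
  NumericMatrix dWr(Cout, C * k * k);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution, stride 2, pad 1, output_padding 1: doubles H and W.
// [[Rcpp::export(name = ".convt2d_fwd")]]
NumericVector convt2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                          int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  if ((int)Wm.n_rows != C) stop("weight/input channel mismatch");
  const int Cout = Wm.n_cols / (k * k);
  const int oH = stride * H, oW = stride * W;
  if (conv_out(oH, k, stride, pad) != H || conv_out(oW, k, stride, pad) != W)
    stop("unsupported transposed-convolution geometry");
  NumericVector y(Cout * oH * oW * N);
  y.attr("dim") = IntegerVector::create(Cout, oH, oW, N);
  for (int n = 0; n < N; ++n) {
    const arma::mat X(const_cast<double*>(x.begin()) + (size_t)C * H * W * n,
                      C, H * W, false, true);
    arma::mat cols = Wm.t() * X;  // (Cout*k*k, H*W)
    double* yb = y.begin() + (size_t)Cout * oH * oW * n;
    col2im_one(cols, yb, Cout, oH, oW, k, stride, pad);
    for (size_t i = 0; i < (size_t)oH * oW; ++i)
      for (int c = 0; c < Cout; ++c) yb[c + Cout * i] += b[c];
  }
  return y;
}

// [[Rcpp::export(name = ".convt2d_bwd")]]
List convt2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                 int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  const int Cout = Wm.n_cols / (k * k);
  const int oH = stride * H, oW = stride * W;
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  arma::mat dW(C, Cout * k * k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    const double* dyb = dy.begin() + (size_t)Cout * oH * oW * n;
    im2col_one(dyb, Cout, oH, oW, k, stride, pad, cols);  // (Cout*k*k, H*W)
    const arma::mat X(const_cast<double*>(x.begin()) + (size_t)C * H * W * n,
                      C, H * W, false, true);
    arma::mat DX(dx.begin() + (size_t)C * H * W * n, C, H * W, false, true);
    DX = Wm * cols;
    dW += X * cols.t();
    for (size_t i = 0; i < (size_t)oH * oW; ++i)
      for (int c = 0; c < Cout; ++c) db[c] += dyb[c + Cout * i];
  }
  NumericMatrix dWr(C, Cout * k * k);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
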