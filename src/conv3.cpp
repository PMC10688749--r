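// 3x3 same-padded convolution kernels for the segmentation engine.
//
// Feature maps are C x (B*H*W) matrices, columns sample-major with
// column-major pixel order (pixel p = y + x*H within a sample).  The
// forward pass builds the 9C x n im2col matrix with contiguous block
// copies (a column strip of constant x is contiguous) and runs a single
// GEMM; the backward pass reuses the same layout for the weight gradient
// and scatters W^T dY back with block adds.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col3(const arma::mat& X, int H, int W, int B, arma::mat& Xcol) {
  const int C = X.n_rows;
  Xcol.zeros();
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int b = 0; b < B; ++b) {
        const int off = b * H * W;
        for (int xo = 0; xo < W; ++xo) {
          const int xi = xo + dx;
          if (xi < 0 || xi >= W) continue;
          const int yo0 = std::max(0, -dy);
          const int yo1 = std::min(H, H - dy);  // exclusive
          const int len = yo1 - yo0;
          if (len <= 0) continue;
          const int dst = off + xo * H + yo0;
          const int src = off + xi * H + yo0 + dy;
          Xcol.submat(k * C, dst, (k + 1) * C - 1, dst + len - 1) =
            X.cols(src, src + len - 1);
        }
      }
      ++k;
    }
  }
}

static arma::mat flatten_w(const arma::cube& Wc) {
  const int Cout = Wc.n_rows, C = Wc.n_cols;
  arma::mat Wm(Cout, 9 * C);
  for (int k = 0; k < 9; ++k) Wm.cols(k * C, (k + 1) * C - 1) = Wc.slice(k);
  return Wm;
}

// [[Rcpp::export]]
List conv3_fwd_cpp(const arma::mat& X, const arma::cube& Wc,
                   const arma::vec& b, int H, int W, int B) {
  const int C = X.n_rows;
  XPtr<arma::mat> xc(new arma::mat(9 * C, X.n_cols), true);
  im2col3(X, H, W, B, *xc);
  arma::mat Y = flatten_w(Wc) * (*xc);
  Y.each_col() += b;
  return List::create(Named("y") = Y, Named("xcol") = xc);
}

// [[Rcpp::export]]
List conv3_bwd_cpp(SEXP xcol_ptr, const arma::cube& Wc,
                   const arma::mat& dY, int H, int W, int B, bool need_dx) {
  XPtr<arma::mat> xc(xcol_ptr);
  const arma::mat& Xcol = *xc;
  const int C = Wc.n_cols, Cout = Wc.n_rows;
  arma::mat Wm = flatten_w(Wc);
  arma::mat dWm = dY * Xcol.t();
  arma::cube dWc(Cout, C, 9);
  for (int k = 0; k < 9; ++k) dWc.slice(k) = dWm.cols(k * C, (k + 1) * C - 1);
  arma::vec db = arma::sum(dY, 1);

  if (!need_dx) {
    return List::create(Named("dx") = R_NilValue, Named("dW") = dWc,
                        Named("db") = db);
  }
  arma::mat dXcol = Wm.t() * dY;       // 9C x n
  arma::mat dX(C, dY.n_cols, arma::fill::zeros);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int b = 0; b < B; ++b) {
        const int off = b * H * W;
        for (int xo = 0; xo < W; ++xo) {
          const int xi = xo + dx;
          if (xi < 0 || xi >= W) continue;
          const int yo0 = std::max(0, -dy);
          const int yo1 = std::min(H, H - dy);
          const int len = yo1 - yo0;
          if (len <= 0) continue;
          const int dst = off + xo * H + yo0;      // position in dY/dXcol
          const int src = off + xi * H + yo0 + dy; // position in X/dX
          dX.cols(src, src + len - 1) +=
            dXcol.submat(k * C, dst, (k + 1) * C - 1, dst + len - 1);
        }
      }
      ++k;
    }
  }
  return List::create(Named("dx") = dX, Named("dW") = dWc, Named("db") = db);
}

// exact GELU x * Phi(x) and its derivative, vectorised in C++
// [[Rcpp::export]]
List gelu_fwd_cpp(const arma::mat& X) {
  arma::mat Ph = 0.5 * (1.0 + arma::erf(X / std::sqrt(2.0)));
  return List::create(Named("y") = X % Ph, Named("ph") = Ph);
}

// [[Rcpp::export]]
arma::mat gelu_bwd_cpp(const arma::mat& dY, const arma::mat& X,
                       const arma::mat& Ph) {
  const double inv_sqrt2pi = 0.3989422804014327;
  return dY % (Ph + X % arma::exp(-0.5 * X % X) * inv_sqrt2pi);
}
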