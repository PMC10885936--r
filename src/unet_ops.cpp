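// Low-level tensor primitives for the 2D convolutional network.
// Tensors are R arrays with dim (H, W, C, N), column-major, so
// x(h, w, c, n) sits at h + H*(w + W*(c + C*n)).
// Convolution weights are (K*K*Cin) x Cout matrices whose row index
// is ki + K*(kj + K*c) for kernel offset (ki, kj) and input channel c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double *x, int H, int W, int C, int K, int pad) {
  arma::mat col(H * W, K * K * C);
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int cc = ki + K * (kj + K * c);
        double *dst = col.colptr(cc);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - pad;
          if (sj < 0 || sj >= W) {
            std::fill(dst + (size_t)j * H, dst + (size_t)(j + 1) * H, 0.0);
            continue;
          }
          const double *src = xc + (size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            int si = i + ki - pad;
            dst[(size_t)j * H + i] = (si < 0 || si >= H) ? 0.0 : src[si];
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(const arma::mat &col, double *x, int H, int W, int C,
                       int K, int pad) {
  for (int c = 0; c < C; ++c) {
    double *xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int cc = ki + K * (kj + K * c);
        const double *src = col.colptr(cc);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          double *dst = xc + (size_t)sj * H;
          for (int i = 0; i < H; ++i) {
            int si = i + ki - pad;
            if (si >= 0 && si < H) dst[si] += src[(size_t)j * H + i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fw")]]
NumericVector conv_fw(NumericVector x, NumericMatrix Wm, NumericVector b,
                      int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int KKC = Wm.nrow(), Cout = Wm.ncol();
  int K = (int)std::lround(std::sqrt((double)KKC / C));
  if (K * K * C != KKC) stop("weight shape inconsistent with input channels");
  arma::mat Wa(Wm.begin(), KKC, Cout, false);
  arma::rowvec ba(b.begin(), Cout);
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, pad);
    arma::mat out = col * Wa;
    out.each_row() += ba;
    std::copy(out.begin(), out.end(), y.begin() + (size_t)n * H * W * Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bw")]]
List conv_bw(NumericVector x, NumericMatrix Wm, NumericVector dy, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int KKC = Wm.nrow(), Cout = Wm.ncol();
  int K = (int)std::lround(std::sqrt((double)KKC / C));
  arma::mat Wa(Wm.begin(), KKC, Cout, false);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dW(KKC, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, pad);
    arma::mat dyn(const_cast<double *>(dy.begin()) + (size_t)n * H * W * Cout,
                  H * W, Cout, false);
    dW += col.t() * dyn;
    db += arma::sum(dyn, 0);
    arma::mat dcol = dyn * Wa.t();
    col2im_add(dcol, dx.begin() + (size_t)n * H * W * C, H, W, C, K, pad);
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(KKC, Cout, dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N); // linear index into (H, W) plane
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (size_t)(c + (size_t)n * C) * H * W;
      size_t off = (size_t)(c + (size_t)n * C) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int bi = 2 * i, bj = 2 * j;
          int best = bi + H * bj;
          double bv = xp[best];
          int cand[3] = {bi + 1 + H * bj, bi + H * (bj + 1), bi + 1 + H * (bj + 1)};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          y[off + i + (size_t)Ho * j] = bv;
          idx[off + i + (size_t)Ho * j] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = dy.attr("dim");
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *dxp = dx.begin() + (size_t)(c + (size_t)n * C) * H * W;
      size_t off = (size_t)(c + (size_t)n * C) * Ho * Wo;
      for (size_t k = 0; k < (size_t)Ho * Wo; ++k)
        dxp[idx[off + k]] += dy[off + k];
    }
  return dx;
}
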