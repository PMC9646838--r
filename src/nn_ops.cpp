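// Low-level batched operators for the compact CNN engine.
// Array layout follows R column-major conventions throughout:
//   feature maps  (H, W, C, N), kernels (kh, kw, C, F).
// Convolutions are stride-1 with "same" zero padding (odd kernels).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold one sample into a (H*W) x (kh*kw*C) patch matrix (transposed
// im2col: each kernel-offset/channel is one contiguous column, filled with
// memcpy-able vertical runs).
static void im2col_t(const double* x, int H, int W, int C,
                     int kh, int kw, int ph, int pw, arma::mat& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        double* dst = cols.colptr(r);
        // output row index = i + H*j maps to source (i + ki - ph, j + kj - pw)
        const int di = ki - ph, dj = kj - pw;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        if (i1 <= i0) continue;
        for (int j = j0; j < j1; ++j) {
          const double* src = x + (i0 + di) + (size_t)H * ((j + dj) + (size_t)W * c);
          std::memcpy(dst + i0 + (size_t)H * j, src, (i1 - i0) * sizeof(double));
        }
      }
    }
  }
}

// Scatter-add the adjoint of im2col_t back onto one input sample.
static void col2im_t(const arma::mat& cols, int H, int W, int C,
                     int kh, int kw, int ph, int pw, double* dx) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const double* src = cols.colptr(r);
        const int di = ki - ph, dj = kj - pw;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        if (i1 <= i0) continue;
        for (int j = j0; j < j1; ++j) {
          double* dst = dx + (i0 + di) + (size_t)H * ((j + dj) + (size_t)W * c);
          const double* s = src + i0 + (size_t)H * j;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("kernel channel count does not match input");
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;

  arma::mat Wm(w.begin(), kh * kw * C, F, false, true);
  NumericVector y((size_t)H * W * F * N);
  arma::mat cols((size_t)H * W, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, ph, pw, cols);
    arma::mat out(y.begin() + (size_t)H * W * F * n, (size_t)H * W, F, false, true);
    out = cols * Wm;                          // (H*W) x F
    for (int f = 0; f < F; ++f) out.col(f) += b[f];
  }
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;

  arma::mat Wm(w.begin(), kh * kw * C, F, false, true);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat dW(kh * kw * C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat cols((size_t)H * W, kh * kw * C);
  arma::mat dcols((size_t)H * W, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(dy.begin() + (size_t)H * W * F * n, (size_t)H * W, F, false, true);
    im2col_t(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, ph, pw, cols);
    dW += cols.t() * dyn;
    db += arma::sum(dyn, 0).t();
    dcols = dyn * Wm.t();                     // (H*W) x (kh*kw*C)
    col2im_t(dcols, H, W, C, kh, kw, ph, pw, dx.begin() + (size_t)H * W * C * n);
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(kh, kw, C, F);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Pooling over non-overlapping s x s windows; trailing rows/cols beyond the
// last full window are dropped. type 0 = max (records argmax), 1 = average.
// [[Rcpp::export]]
List nn_pool_fwd(NumericVector x, int s, int type) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / s, Wo = W / s;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(type == 0 ? (size_t)Ho * Wo * C * N : 0);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          if (type == 0) {
            double best = -std::numeric_limits<double>::infinity();
            size_t bi = 0;
            for (int dj = 0; dj < s; ++dj)
              for (int di = 0; di < s; ++di) {
                const size_t p = base + (i * s + di) + (size_t)H * (j * s + dj);
                if (x[p] > best) { best = x[p]; bi = p; }
              }
            y[o] = best;
            idx[o] = (int)bi;
          } else {
            double acc = 0.0;
            for (int dj = 0; dj < s; ++dj)
              for (int di = 0; di < s; ++di)
                acc += x[base + (i * s + di) + (size_t)H * (j * s + dj)];
            y[o] = acc / (s * s);
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_pool_bwd(NumericVector dy, IntegerVector idx,
                          IntegerVector xdim, int s, int type) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / s, Wo = W / s;
  NumericVector dx((size_t)H * W * C * N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          if (type == 0) {
            dx[idx[o]] += dy[o];
          } else {
            const double g = dy[o] / (s * s);
            for (int dj = 0; dj < s; ++dj)
              for (int di = 0; di < s; ++di)
                dx[base + (i * s + di) + (size_t)H * (j * s + dj)] += g;
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}
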