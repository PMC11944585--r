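// Convolution and pooling kernels for the colony classifier.
//
// All convolutions are 3x3 (or k x k, k odd), stride 1, zero "same" padding,
// implemented as im2col + GEMM so the heavy lifting runs in BLAS. Layouts
// follow R's column-major array conventions:
//   activations: (H, W, C, N) numeric arrays
//   conv weights: (k*k*C, F) matrices, rows ordered di-fastest then dj then c,
//                 i.e. the natural flattening of an R array dim (k, k, C, F)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const double* x, int H, int W, int C, int k) {
  const int p = k / 2, HW = H * W;
  arma::mat col(k * k * C, HW, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        const int oi = di - p, oj = dj - p;  // source offset
        for (int j = 0; j < W; ++j) {
          const int sj = j + oj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
          double* dst = col.colptr(j * H) + row;  // stride k*k*C per pixel
          const double* src = xc + (size_t)sj * H + oi;
          for (int i = i0; i < i1; ++i)
            dst[(size_t)i * col.n_rows] = src[i];
        }
      }
    }
  }
  return col;
}

static void col2im_add(const arma::mat& col, double* x, int H, int W, int C,
                       int k) {
  const int p = k / 2, HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * HW;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        const int oi = di - p, oj = dj - p;
        for (int j = 0; j < W; ++j) {
          const int sj = j + oj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
          const double* src = col.colptr(j * H) + row;
          double* dst = xc + (size_t)sj * H + oi;
          for (int i = i0; i < i1; ++i)
            dst[i] += src[(size_t)i * col.n_rows];
        }
      }
    }
  }
}

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector make4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.ncol();
  const int k = (int)std::lround(std::sqrt((double)w.nrow() / C));
  if (k * k * C != w.nrow()) stop("weight rows incompatible with input depth");
  arma::mat wm(w.begin(), w.nrow(), F, false);
  arma::rowvec bv(b.begin(), F);
  NumericVector y = make4(H, W, F, N);
  const size_t in_sz = (size_t)H * W * C, out_sz = (size_t)H * W * F;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + n * in_sz, H, W, C, k);
    arma::mat out = col.t() * wm;          // (H*W, F)
    out.each_row() += bv;
    std::copy(out.begin(), out.end(), y.begin() + n * out_sz);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericMatrix w, NumericVector dy) {
  IntegerVector d = dims4(x), dd = dims4(dy);
  const int H = d[0], W = d[1], C = d[2], N = d[3], F = dd[2];
  const int k = (int)std::lround(std::sqrt((double)w.nrow() / C));
  arma::mat wm(w.begin(), w.nrow(), F, false);
  NumericVector dx = make4(H, W, C, N);
  arma::mat dw(w.nrow(), F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  const size_t in_sz = (size_t)H * W * C, out_sz = (size_t)H * W * F;
  for (int n = 0; n < N; ++n) {
    arma::mat dym(dy.begin() + n * out_sz, (size_t)H * W, F, false);
    arma::mat col = im2col(x.begin() + n * in_sz, H, W, C, k);
    dw += col * dym;
    db += arma::sum(dym, 0);
    arma::mat dcol = wm * dym.t();         // (k*k*C, H*W)
    col2im_add(dcol, dx.begin() + n * in_sz, H, W, C, k);
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dw),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; idx stores the winning linear offset within each
// input (H, W) slice so the backward pass is a scatter.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("pooling needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector idx = make4i(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const size_t slices = (size_t)C * N;
  for (size_t s = 0; s < slices; ++s) {
    const double* xs = xp + s * H * W;
    double* ys = yp + s * Ho * Wo;
    int* is = ip + s * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int base = (2 * j) * H + 2 * i;
        int best = base;
        double bv = xs[base];
        const int cand[3] = {base + 1, base + H, base + H + 1};
        for (int t = 0; t < 3; ++t)
          if (xs[cand[t]] > bv) { bv = xs[cand[t]]; best = cand[t]; }
        ys[j * Ho + i] = bv;
        is[j * Ho + i] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dy, int H,
                             int W) {
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = make4(H, W, C, N);
  const size_t slices = (size_t)C * N;
  for (size_t s = 0; s < slices; ++s) {
    const int* is = idx.begin() + s * Ho * Wo;
    const double* dys = dy.begin() + s * Ho * Wo;
    double* dxs = dx.begin() + s * H * W;
    for (int t = 0; t < Ho * Wo; ++t) dxs[is[t]] += dys[t];
  }
  return dx;
}
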