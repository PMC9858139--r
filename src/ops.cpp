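// Hot numeric kernels: valid-padding convolution via im2col + GEMM,
// 8-connectivity component labelling, and the 7x7 linking correlation
// of the spiking cortical model (zero padding outside the lattice).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Activation layout: one image is a column vector of length H*W*C with
// index i + H*j + H*W*c (row i, column j, channel c; all 0-based).
// Patch row order inside im2col: p = di + k*dj + k*k*c.

static void im2col(const arma::vec& x, int H, int W, int C,
                   int k, int stride, arma::mat& col) {
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.memptr() + (std::size_t)H * W * c;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int pos = io + Ho * jo;
        double* dst = col.colptr(pos) + (std::size_t)k * k * c;
        const int i0 = io * stride, j0 = jo * stride;
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di)
            dst[di + k * dj] = xc[(i0 + di) + H * (j0 + dj)];
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv2d_forward_cpp(const arma::mat& A, int H, int W, int C,
                             const arma::mat& Wmat, const arma::vec& bias,
                             int k, int stride) {
  const int B = A.n_cols;
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  const int npos = Ho * Wo;
  const int Cout = Wmat.n_rows;
  arma::mat out((std::size_t)npos * Cout, B);
  arma::mat col((std::size_t)k * k * C, npos);
  for (int b = 0; b < B; ++b) {
    im2col(A.col(b), H, W, C, k, stride, col);
    arma::mat o = Wmat * col;          // Cout x npos
    o.each_col() += bias;
    out.col(b) = arma::vectorise(o.t());
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(const arma::mat& A, const arma::mat& dOut,
                         int H, int W, int C, const arma::mat& Wmat,
                         int k, int stride) {
  const int B = A.n_cols;
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  const int npos = Ho * Wo;
  const int Cout = Wmat.n_rows;
  arma::mat dW(arma::size(Wmat), arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dA((std::size_t)H * W * C, B, arma::fill::zeros);
  arma::mat col((std::size_t)k * k * C, npos);
  for (int b = 0; b < B; ++b) {
    im2col(A.col(b), H, W, C, k, stride, col);
    arma::mat g(dOut.colptr(b), npos, Cout); // npos x Cout view copy
    arma::mat gt = g.t();                    // Cout x npos
    dW += gt * col.t();
    db += arma::sum(gt, 1);
    arma::mat dcol = Wmat.t() * gt;          // k*k*C x npos
    // col2im scatter-add
    double* dst0 = dA.colptr(b);
    for (int c = 0; c < C; ++c) {
      double* dc = dst0 + (std::size_t)H * W * c;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          const int pos = io + Ho * jo;
          const double* src = dcol.colptr(pos) + (std::size_t)k * k * c;
          const int i0 = io * stride, j0 = jo * stride;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di)
              dc[(i0 + di) + H * (j0 + dj)] += src[di + k * dj];
        }
      }
    }
  }
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// 8-connectivity connected-component labelling of a binary matrix.
// [[Rcpp::export]]
IntegerMatrix cc_label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Correlation of Y with kernel Wk (odd size), zero padding at borders:
// L(i,j) = sum_{k,l} Wk(k,l) Y(i+k-r, j+l-r).
// [[Rcpp::export]]
arma::mat linking_corr_cpp(const arma::mat& Y, const arma::mat& Wk) {
  const int H = Y.n_rows, W = Y.n_cols;
  const int s = Wk.n_rows, r = s / 2;
  arma::mat L(H, W, arma::fill::zeros);
  for (int dj = -r; dj <= r; ++dj) {
    for (int di = -r; di <= r; ++di) {
      const double w = Wk(di + r, dj + r);
      if (w == 0.0) continue;
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      if (i0 >= i1 || j0 >= j1) continue;
      L.submat(i0, j0, i1 - 1, j1 - 1) +=
        w * Y.submat(i0 + di, j0 + dj, i1 - 1 + di, j1 - 1 + dj);
    }
  }
  return L;
}

// Elementwise softplus, overflow-safe.
// [[Rcpp::export]]
NumericMatrix softplus_cpp(const NumericMatrix& x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xi = x.begin(); double* yi = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = xi[i];
    yi[i] = (v > 0 ? v : 0) + log1p(std::exp(-std::fabs(v)));
  }
  return y;
}

// dy * sigmoid(x), elementwise (softplus backward).
// [[Rcpp::export]]
NumericMatrix softplus_grad_cpp(const NumericMatrix& x,
                                const NumericMatrix& dy) {
  NumericMatrix g(x.nrow(), x.ncol());
  const double* xi = x.begin(); const double* di = dy.begin();
  double* gi = g.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    gi[i] = di[i] / (1.0 + std::exp(-xi[i]));
  return g;
}

// Per-channel affine y = x * scale[c] + shift[c] for (HW*C) x B input.
// [[Rcpp::export]]
NumericMatrix bn_affine_cpp(const NumericMatrix& x, const NumericVector& scale,
                            const NumericVector& shift, int HW) {
  const int C = scale.size();
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xi = x.begin(); double* yi = y.begin();
  const R_xlen_t ncol = x.ncol(), nrow = x.nrow();
  for (R_xlen_t b = 0; b < ncol; ++b) {
    const double* xc = xi + b * nrow; double* yc = yi + b * nrow;
    for (int c = 0; c < C; ++c) {
      const double s = scale[c], t = shift[c];
      const R_xlen_t o = (R_xlen_t)c * HW;
      for (int p = 0; p < HW; ++p) yc[o + p] = xc[o + p] * s + t;
    }
  }
  return y;
}

// Per-channel mean and population variance over spatial x batch.
// [[Rcpp::export]]
List bn_stats_cpp(const NumericMatrix& x, int HW, int C) {
  const R_xlen_t B = x.ncol(), nrow = x.nrow();
  NumericVector s1(C), s2(C);
  const double* xi = x.begin();
  for (R_xlen_t b = 0; b < B; ++b) {
    const double* xc = xi + b * nrow;
    for (int c = 0; c < C; ++c) {
      double a1 = 0, a2 = 0;
      const R_xlen_t o = (R_xlen_t)c * HW;
      for (int p = 0; p < HW; ++p) { const double v = xc[o + p]; a1 += v; a2 += v * v; }
      s1[c] += a1; s2[c] += a2;
    }
  }
  const double N = (double)HW * B;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    mu[c] = s1[c] / N;
    var[c] = s2[c] / N - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// Batch-norm backward: given cached input x, batch mu/sd, gamma, and
// upstream dy, return dgamma, dxi, dx in two passes.
// [[Rcpp::export]]
List bn_backward_cpp(const NumericMatrix& x, const NumericMatrix& dy,
                     const NumericVector& mu, const NumericVector& sd,
                     const NumericVector& gamma, int HW) {
  const int C = mu.size();
  const R_xlen_t B = x.ncol(), nrow = x.nrow();
  NumericVector dgamma(C), dxi(C);
  const double* xi = x.begin(); const double* di = dy.begin();
  for (R_xlen_t b = 0; b < B; ++b) {
    const double* xc = xi + b * nrow; const double* dc = di + b * nrow;
    for (int c = 0; c < C; ++c) {
      double a1 = 0, a2 = 0;
      const double m = mu[c], s = sd[c];
      const R_xlen_t o = (R_xlen_t)c * HW;
      for (int p = 0; p < HW; ++p) {
        const double d = dc[o + p];
        a1 += d * (xc[o + p] - m) / s;
        a2 += d;
      }
      dgamma[c] += a1; dxi[c] += a2;
    }
  }
  const double N = (double)HW * B;
  NumericMatrix dx(nrow, B);
  double* oi = dx.begin();
  for (R_xlen_t b = 0; b < B; ++b) {
    const double* xc = xi + b * nrow; const double* dc = di + b * nrow;
    double* oc = oi + b * nrow;
    for (int c = 0; c < C; ++c) {
      const double m = mu[c], s = sd[c];
      const double gs = gamma[c] / s;
      const double mdg = dgamma[c] / N, mdx = dxi[c] / N;
      const R_xlen_t o = (R_xlen_t)c * HW;
      for (int p = 0; p < HW; ++p) {
        const double xh = (xc[o + p] - m) / s;
        oc[o + p] = gs * (dc[o + p] - mdx - xh * mdg);
      }
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dxi"] = dxi, _["dx"] = dx);
}
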