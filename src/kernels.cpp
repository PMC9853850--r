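// Performance-critical kernels of the 1D-CNN layers.
//
// Convolutions are evaluated as one im2col GEMM per layer; the patch
// matrix is rebuilt in the backward pass from the cached layer input
// rather than round-tripped through R. Inputs are wrapped as Armadillo
// views over the R memory (no copies); only outputs are allocated. Data
// layout matches the R side: sequence arrays are (time, batch, channels),
// column-major, so the (time, batch) plane flattens to the rows of the
// per-channel matrices. All randomness (dropout masks, initialization)
// stays on the R side, so seeded runs are reproducible end to end.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube cube_view(Rcpp::NumericVector a) {
  Rcpp::IntegerVector d = a.attr("dim");
  return cube(a.begin(), d[0], d[1], d[2], false, true);
}

// im2col for "same" 1-D convolution: column (c*K + k) of the result holds
// input channel c shifted by (k - pad), zero-padded at the edges.
static mat im2col1d(const cube& a, const int K) {
  const int L = a.n_rows, N = a.n_cols, C = a.n_slices;
  const int pad = (K - 1) / 2;
  mat P(static_cast<uword>(L) * N, static_cast<uword>(K) * C,
        fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int shift = k - pad; // source index offset
      double* dst = P.colptr(static_cast<uword>(c) * K + k);
      for (int n = 0; n < N; ++n) {
        const double* src = a.slice_colptr(c, n);
        const int l0 = std::max(0, -shift);
        const int l1 = std::min(L, L - shift);
        for (int l = l0; l < l1; ++l) {
          dst[static_cast<uword>(n) * L + l] = src[l + shift];
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
Rcpp::NumericVector cpp_conv_fwd(Rcpp::NumericVector a_,
                                 const arma::mat& w, const arma::vec& b,
                                 const int K) {
  cube a = cube_view(a_);
  mat P = im2col1d(a, K);
  const uword rows = P.n_rows, F = w.n_cols;
  Rcpp::NumericVector out_(static_cast<R_xlen_t>(rows) * F);
  mat y(out_.begin(), rows, F, false, true);
  y = P * w;
  y.each_row() += b.t();
  out_.attr("dim") = Rcpp::IntegerVector::create(a.n_rows, a.n_cols, F);
  return out_;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
Rcpp::List cpp_conv_bwd(Rcpp::NumericVector a_, const arma::mat& w,
                        Rcpp::NumericVector dy_, const int K) {
  cube a = cube_view(a_);
  const int L = a.n_rows, N = a.n_cols, C = a.n_slices;
  const uword F = w.n_cols;
  mat dy(dy_.begin(), static_cast<uword>(L) * N, F, false, true);
  mat P = im2col1d(a, K);
  mat dW = P.t() * dy;
  vec db = sum(dy, 0).t();
  mat dP = dy * w.t();
  const int pad = (K - 1) / 2;
  Rcpp::NumericVector da_(static_cast<R_xlen_t>(L) * N * C);
  cube da(da_.begin(), L, N, C, false, true);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int shift = k - pad;
      const double* src = dP.colptr(static_cast<uword>(c) * K + k);
      for (int n = 0; n < N; ++n) {
        double* dst = da.slice_colptr(c, n);
        const int l0 = std::max(0, -shift);
        const int l1 = std::min(L, L - shift);
        for (int l = l0; l < l1; ++l) {
          dst[l + shift] += src[static_cast<uword>(n) * L + l];
        }
      }
    }
  }
  da_.attr("dim") = Rcpp::IntegerVector::create(L, N, C);
  return Rcpp::List::create(Rcpp::Named("dinput") = da_,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".cpp_bn_fwd")]]
Rcpp::List cpp_bn_fwd(Rcpp::NumericVector x_, const int f,
                      const arma::vec& gamma, const arma::vec& beta,
                      const arma::vec& run_mean, const arma::vec& run_var,
                      const bool training, const double momentum,
                      const double eps) {
  const uword n = x_.size() / f;
  mat x(x_.begin(), n, f, false, true);
  vec mu(f), v(f);
  if (training) {
    for (int j = 0; j < f; ++j) {
      const double* xc = x.colptr(j);
      double s = 0, s2 = 0;
      for (uword i = 0; i < n; ++i) {
        s += xc[i];
        s2 += xc[i] * xc[i];
      }
      mu(j) = s / n;
      v(j) = s2 / n - mu(j) * mu(j);
      if (v(j) < 0) v(j) = 0;
    }
  } else {
    mu = run_mean;
    v = run_var;
  }
  vec istd = 1.0 / sqrt(v + eps);
  Rcpp::NumericVector y_(x_.size()), xhat_(x_.size());
  mat y(y_.begin(), n, f, false, true);
  mat xhat(xhat_.begin(), n, f, false, true);
  for (int j = 0; j < f; ++j) {
    const double m = mu(j), s = istd(j), g = gamma(j), bb = beta(j);
    const double* xc = x.colptr(j);
    double* xh = xhat.colptr(j);
    double* yc = y.colptr(j);
    for (uword i = 0; i < n; ++i) {
      xh[i] = (xc[i] - m) * s;
      yc[i] = xh[i] * g + bb;
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("y") = y_, Rcpp::Named("xhat") = xhat_,
      Rcpp::Named("istd") = istd);
  if (training) {
    out["new_mean"] = momentum * run_mean + (1 - momentum) * mu;
    out["new_var"] = momentum * run_var + (1 - momentum) * v;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
Rcpp::List cpp_bn_bwd(Rcpp::NumericVector dy_, Rcpp::NumericVector xhat_,
                      const arma::vec& istd, const arma::vec& gamma,
                      const bool training) {
  const int f = istd.n_elem;
  const uword n = dy_.size() / f;
  mat dy(dy_.begin(), n, f, false, true);
  mat xhat(xhat_.begin(), n, f, false, true);
  vec dgamma(f), dbeta(f);
  Rcpp::NumericVector dx_(dy_.size());
  mat dx(dx_.begin(), n, f, false, true);
  for (int j = 0; j < f; ++j) {
    const double* dyc = dy.colptr(j);
    const double* xh = xhat.colptr(j);
    double sg = 0, sb = 0;
    for (uword i = 0; i < n; ++i) {
      sg += dyc[i] * xh[i];
      sb += dyc[i];
    }
    dgamma(j) = sg;
    dbeta(j) = sb;
    const double gi = gamma(j) * istd(j);
    double* dxc = dx.colptr(j);
    if (training) {
      const double mb = sb / n, mg = sg / n;
      for (uword i = 0; i < n; ++i) {
        dxc[i] = gi * (dyc[i] - mb - xh[i] * mg);
      }
    } else {
      for (uword i = 0; i < n; ++i) dxc[i] = gi * dyc[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dinput") = dx_,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = ".cpp_relu_fwd")]]
Rcpp::NumericVector cpp_relu_fwd(Rcpp::NumericVector x) {
  const R_xlen_t n = x.size();
  Rcpp::NumericVector y(n);
  const double* px = x.begin();
  double* py = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) py[i] = px[i] > 0 ? px[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
Rcpp::NumericVector cpp_relu_bwd(Rcpp::NumericVector dy,
                                 Rcpp::NumericVector y) {
  const R_xlen_t n = dy.size();
  Rcpp::NumericVector dx(n);
  const double* pd = dy.begin();
  const double* py = y.begin();
  double* px = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) px[i] = py[i] > 0 ? pd[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// [[Rcpp::export(name = ".cpp_pool_fwd")]]
Rcpp::List cpp_pool_fwd(Rcpp::NumericVector a_, const int p) {
  cube a = cube_view(a_);
  const int L = a.n_rows, N = a.n_cols, F = a.n_slices;
  const int Lo = L / p;
  Rcpp::NumericVector y_(static_cast<R_xlen_t>(Lo) * N * F);
  cube y(y_.begin(), Lo, N, F, false, true);
  Rcpp::IntegerVector wh(static_cast<R_xlen_t>(Lo) * N * F);
  int* whp = wh.begin();
  R_xlen_t o = 0;
  for (int f = 0; f < F; ++f) {
    for (int n = 0; n < N; ++n) {
      const double* src = a.slice_colptr(f, n);
      double* dst = y.slice_colptr(f, n);
      for (int l = 0; l < Lo; ++l) {
        const double* blk = src + static_cast<uword>(l) * p;
        double best = blk[0];
        int bi = 0;
        for (int r = 1; r < p; ++r) {
          if (blk[r] > best) { best = blk[r]; bi = r; }
        }
        dst[l] = best;
        whp[o++] = bi;
      }
    }
  }
  y_.attr("dim") = Rcpp::IntegerVector::create(Lo, N, F);
  return Rcpp::List::create(Rcpp::Named("out") = y_,
                            Rcpp::Named("wh") = wh);
}

// [[Rcpp::export(name = ".cpp_pool_bwd")]]
Rcpp::NumericVector cpp_pool_bwd(Rcpp::NumericVector dy_,
                                 const Rcpp::IntegerVector& wh,
                                 const int L, const int p) {
  cube dy = cube_view(dy_);
  const int Lo = dy.n_rows, N = dy.n_cols, F = dy.n_slices;
  Rcpp::NumericVector da_(static_cast<R_xlen_t>(L) * N * F);
  cube da(da_.begin(), L, N, F, false, true);
  const int* whp = wh.begin();
  R_xlen_t o = 0;
  for (int f = 0; f < F; ++f) {
    for (int n = 0; n < N; ++n) {
      const double* src = dy.slice_colptr(f, n);
      double* dst = da.slice_colptr(f, n);
      for (int l = 0; l < Lo; ++l) {
        dst[static_cast<uword>(l) * p + whp[o++]] = src[l];
      }
    }
  }
  da_.attr("dim") = Rcpp::IntegerVector::create(L, N, F);
  return da_;
}
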