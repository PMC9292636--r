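// Fused im2col + GEMM convolution passes (Armadillo, single allocation per
// call). Bias is omitted: every convolution is followed by batch
// normalization, whose shift parameter absorbs it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void gather_cols(const arma::mat& x, const IntegerMatrix& nbr,
                        int n_batch, arma::mat& xcol) {
  const int hw = nbr.nrow();
  const int K = nbr.ncol();
  const int C = x.n_cols;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    for (int k = 0; k < K; ++k) {
      double* oc = xcol.colptr(c * K + k);
      const int* nb = &nbr(0, k);
      for (int b = 0; b < n_batch; ++b) {
        const double* xb = xc + (size_t)b * hw;
        double* ob = oc + (size_t)b * hw;
        for (int p = 0; p < hw; ++p) {
          int idx = nb[p];
          ob[p] = (idx > 0) ? xb[idx - 1] : 0.0;
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv_forward(const arma::mat& x, const arma::mat& W,
                       const IntegerMatrix& nbr, int n_batch) {
  arma::mat xcol(x.n_rows, W.n_rows);
  gather_cols(x, nbr, n_batch, xcol);
  return xcol * W;
}

// [[Rcpp::export]]
List conv_backward(const arma::mat& x, const arma::mat& W, const arma::mat& dz,
                   const IntegerMatrix& nbr, int n_batch) {
  const int hw = nbr.nrow();
  const int K = nbr.ncol();
  const int C = x.n_cols;
  arma::mat xcol(x.n_rows, W.n_rows);
  gather_cols(x, nbr, n_batch, xcol);
  arma::mat dW = xcol.t() * dz;
  arma::mat dxcol = dz * W.t();
  arma::mat dx(x.n_rows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = dx.colptr(c);
    for (int k = 0; k < K; ++k) {
      const double* oc = dxcol.colptr(c * K + k);
      const int* nb = &nbr(0, k);
      for (int b = 0; b < n_batch; ++b) {
        double* xb = xc + (size_t)b * hw;
        const double* ob = oc + (size_t)b * hw;
        for (int p = 0; p < hw; ++p) {
          int idx = nb[p];
          if (idx > 0) xb[idx - 1] += ob[p];
        }
      }
    }
  }
  return List::create(Named("dW") = dW, Named("dx") = dx);
}

// [[Rcpp::export]]
List bn_fwd_train(const arma::mat& x, const arma::vec& gamma,
                  const arma::vec& beta, double eps) {
  const int n = x.n_rows, C = x.n_cols;
  arma::vec mu(C), va(C), invstd(C);
  arma::mat xhat(n, C), y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += xc[i]; }
    double m = s / n;
    for (int i = 0; i < n; ++i) { double d = xc[i] - m; s2 += d * d; }
    double v = s2 / n;
    double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m; va[c] = v; invstd[c] = is;
    double* xh = xhat.colptr(c);
    double* yc = y.colptr(c);
    const double g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      double h = (xc[i] - m) * is;
      xh[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("invstd") = invstd, Named("mu") = mu,
                      Named("va") = va);
}

// [[Rcpp::export]]
arma::mat bn_fwd_eval(const arma::mat& x, const arma::vec& mean,
                      const arma::vec& var, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  const int n = x.n_rows, C = x.n_cols;
  arma::mat y(n, C);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mean[c];
    const double* xc = x.colptr(c);
    double* yc = y.colptr(c);
    for (int i = 0; i < n; ++i) yc[i] = g * (xc[i] - m) * is + b;
  }
  return y;
}

// [[Rcpp::export]]
List bn_bwd(const arma::mat& dy, const arma::mat& xhat,
            const arma::vec& invstd, const arma::vec& gamma) {
  const int n = dy.n_rows, C = dy.n_cols;
  arma::vec dgamma(C), dbeta(C);
  arma::mat dx(n, C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.colptr(c);
    const double* xh = xhat.colptr(c);
    double sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) { sg += dyc[i] * xh[i]; sb += dyc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double a = gamma[c] * invstd[c];
    const double mb = sb / n, mg = sg / n;
    double* dxc = dx.colptr(c);
    for (int i = 0; i < n; ++i) dxc[i] = a * (dyc[i] - mb - xh[i] * mg);
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
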