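// Hot kernels for the 1-D CNN engine: 'same' convolution (zero-padded)
// over segment-major batches, non-overlapping max pooling, and per-channel
// batch normalization. A batch of B segments of length L with C channels
// is an (L*B) x C matrix whose first L rows belong to segment 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Wbig stacks the k kernel taps row-wise: tap o occupies rows
// [(o-1)*C, o*C). Zero padding at segment edges = shifted row-range adds.
// [[Rcpp::export]]
arma::mat cpp_conv1d_fw(const arma::mat& X, const arma::mat& Wbig,
                        const arma::vec& bias, const int L, const int B) {
  const int C = X.n_cols;
  const int k = Wbig.n_rows / C;
  const int pad = (k - 1) / 2;
  const int F = Wbig.n_cols;
  mat Y(X.n_rows, F);
  Y.each_row() = bias.t();
  for (int o = 0; o < k; ++o) {
    const int off = o - pad;  // output row reads input row + off
    const mat Wo = Wbig.rows(o * C, (o + 1) * C - 1);
    for (int b = 0; b < B; ++b) {
      const int base = b * L;
      const int out0 = std::max(0, -off);
      const int out1 = L - 1 - std::max(0, off);
      if (out1 < out0) continue;
      Y.rows(base + out0, base + out1) +=
        X.rows(base + out0 + off, base + out1 + off) * Wo;
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw(const arma::mat& X, const arma::mat& dY,
                         const arma::mat& Wbig, const int L, const int B) {
  const int C = X.n_cols;
  const int k = Wbig.n_rows / C;
  const int pad = (k - 1) / 2;
  mat dWbig(Wbig.n_rows, Wbig.n_cols, fill::zeros);
  mat dX(X.n_rows, C, fill::zeros);
  for (int o = 0; o < k; ++o) {
    const int off = o - pad;
    const mat Wo = Wbig.rows(o * C, (o + 1) * C - 1);
    mat dWo(C, Wbig.n_cols, fill::zeros);
    for (int b = 0; b < B; ++b) {
      const int base = b * L;
      const int out0 = std::max(0, -off);
      const int out1 = L - 1 - std::max(0, off);
      if (out1 < out0) continue;
      dWo += X.rows(base + out0 + off, base + out1 + off).t() *
        dY.rows(base + out0, base + out1);
      dX.rows(base + out0 + off, base + out1 + off) +=
        dY.rows(base + out0, base + out1) * Wo.t();
    }
    dWbig.rows(o * C, (o + 1) * C - 1) = dWo;
  }
  return Rcpp::List::create(Rcpp::Named("dWbig") = dWbig,
                            Rcpp::Named("db") = sum(dY, 0).t(),
                            Rcpp::Named("dX") = dX);
}

// Max over non-overlapping windows of p rows per channel; `arg` holds
// 1-based linear indices into X (column-major) for the backward scatter.
// p must divide L; windows never straddle segments because p | L.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(const arma::mat& X, const int p) {
  const int N = X.n_rows, C = X.n_cols;
  const int M = N / p;
  mat Y(M, C);
  umat arg(M, C);
  for (int c = 0; c < C; ++c) {
    const double* col = X.colptr(c);
    for (int j = 0; j < M; ++j) {
      int best = j * p;
      double bv = col[best];
      for (int o = 1; o < p; ++o) {
        const double v = col[j * p + o];
        if (v > bv) { bv = v; best = j * p + o; }
      }
      Y(j, c) = bv;
      arg(j, c) = (uword)(c * N + best + 1);  // 1-based linear index
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("arg") = arg);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bw(const arma::mat& dY, const arma::umat& arg,
                         const int n_in) {
  mat dX(n_in, dY.n_cols, fill::zeros);
  double* out = dX.memptr();
  const double* g = dY.memptr();
  const uword* a = arg.memptr();
  const uword n = dY.n_elem;
  for (uword i = 0; i < n; ++i) out[a[i] - 1] = g[i];
  return dX;
}

// Training-mode batch norm over rows (batch x position) per channel.
// Single pass per column, no broadcast temporaries.
// [[Rcpp::export]]
Rcpp::List cpp_bn_fw(const arma::mat& X, const arma::vec& gamma,
                     const arma::vec& beta, const double eps) {
  const uword N = X.n_rows, C = X.n_cols;
  mat xhat(N, C), Y(N, C);
  vec mu(C), v(C), inv(C);
  for (uword c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double s = 0.0, ss = 0.0;
    for (uword i = 0; i < N; ++i) { s += x[i]; ss += x[i] * x[i]; }
    const double m = s / N;
    const double var = ss / N - m * m;
    const double iv = 1.0 / std::sqrt(var + eps);
    mu(c) = m; v(c) = var; inv(c) = iv;
    const double g = gamma(c), b = beta(c);
    double* xh = xhat.colptr(c);
    double* y = Y.colptr(c);
    for (uword i = 0; i < N; ++i) {
      xh[i] = (x[i] - m) * iv;
      y[i] = xh[i] * g + b;
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("mu") = mu,
                            Rcpp::Named("var") = v,
                            Rcpp::Named("inv") = inv,
                            Rcpp::Named("xhat") = xhat);
}

// Inference-mode batch norm with frozen statistics.
// [[Rcpp::export]]
arma::mat cpp_bn_apply(const arma::mat& X, const arma::vec& gamma,
                       const arma::vec& beta, const arma::vec& mean_,
                       const arma::vec& var_, const double eps) {
  const uword N = X.n_rows, C = X.n_cols;
  mat Y(N, C);
  for (uword c = 0; c < C; ++c) {
    const double iv = gamma(c) / std::sqrt(var_(c) + eps);
    const double b = beta(c) - mean_(c) * iv;
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    for (uword i = 0; i < N; ++i) y[i] = x[i] * iv + b;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_bw(const arma::mat& dY, const arma::mat& xhat,
                     const arma::vec& inv, const arma::vec& gamma) {
  const uword N = dY.n_rows, C = dY.n_cols;
  mat dX(N, C);
  vec dgamma(C), dbeta(C);
  for (uword c = 0; c < C; ++c) {
    const double* g = dY.colptr(c);
    const double* xh = xhat.colptr(c);
    double s1 = 0.0, s2 = 0.0;
    for (uword i = 0; i < N; ++i) { s1 += g[i]; s2 += g[i] * xh[i]; }
    dbeta(c) = s1;
    dgamma(c) = s2;
    const double ga = gamma(c);
    const double m1 = ga * s1 / N, m2 = ga * s2 / N;
    const double iv = inv(c);
    double* o = dX.colptr(c);
    for (uword i = 0; i < N; ++i)
      o[i] = (ga * g[i] - m1 - xh[i] * m2) * iv;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
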