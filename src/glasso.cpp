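// Graphical lasso: L1-penalised sparse inverse covariance estimation by
// blockwise coordinate descent on the covariance estimate W, with the inner
// lasso subproblem solved by cyclic coordinate descent.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Solve one glasso problem. S must be symmetric PSD. When warm_W has the
// right dimension it is used as the starting covariance estimate (the
// penalised diagonal is re-imposed), which makes sweeps over many similar
// problems (adjacent sliding windows) cheap.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda, int max_iter,
                      double tol, Rcpp::Nullable<Rcpp::NumericMatrix> warm_W) {
  const int p = S.n_rows;
  mat W;
  bool warm = false;
  if (warm_W.isNotNull()) {
    Rcpp::NumericMatrix wm(warm_W);
    if (wm.nrow() == p && wm.ncol() == p) {
      W = Rcpp::as<mat>(wm);
      warm = true;
    }
  }
  if (!warm) W = S;
  W.diag() = S.diag() + lambda;

  // B(,j) holds the lasso coefficients of column j's subproblem
  mat B(p, p, fill::zeros);
  double max_delta = datum::inf;
  int iter = 0;
  const int inner_max = 200;
  // inner tolerance tied to the scale of S
  const double s_scale = std::max(1e-12, mean(mean(abs(S))));
  const double inner_tol = tol * s_scale * 1e-2;

  for (iter = 0; iter < max_iter; ++iter) {
    max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      // indices except j
      uvec idx(p - 1);
      for (int i = 0, k = 0; i < p; ++i) if (i != j) idx[k++] = i;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      beta = beta.elem(idx);

      // cyclic coordinate descent for
      //   min 0.5 b' W11 b - s12' b + lambda ||b||_1
      for (int it = 0; it < inner_max; ++it) {
        double delta = 0.0;
        for (int i = 0; i < p - 1; ++i) {
          double grad = s12[i] - dot(W11.col(i), beta) + W11(i, i) * beta[i];
          double bnew = soft_threshold(grad, lambda) / W11(i, i);
          double d = std::abs(bnew - beta[i]);
          if (d > delta) delta = d;
          beta[i] = bnew;
        }
        if (delta < inner_tol) break;
      }

      vec w12 = W11 * beta;
      for (int i = 0; i < p - 1; ++i) {
        double d = std::abs(W(idx[i], j) - w12[i]);
        if (d > max_delta) max_delta = d;
        W(idx[i], j) = w12[i];
        W(j, idx[i]) = w12[i];
        B(idx[i], j) = beta[i];
      }
    }
    if (max_delta < tol) { ++iter; break; }
  }

  // recover the precision matrix from (W, B)
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    for (int i = 0, k = 0; i < p; ++i) if (i != j) idx[k++] = i;
    vec beta = B.col(j);
    beta = beta.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double theta_jj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = theta_jj;
    for (int i = 0; i < p - 1; ++i) Theta(idx[i], j) = -beta[i] * theta_jj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("w") = W,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = (max_delta < tol));
}

// Weighted covariance of rows [start, start+len) of X under taper weights w
// (sum(w) == 1): S = sum_t w_t (x_t - mu)(x_t - mu)'.
// [[Rcpp::export]]
arma::mat weighted_cov_cpp(const arma::mat& X, int start, const arma::vec& w) {
  const int len = w.n_elem;
  mat Xw = X.rows(start, start + len - 1);
  rowvec mu = w.t() * Xw;
  Xw.each_row() -= mu;
  mat Xs = Xw;
  Xs.each_col() %= w;
  mat S = Xs.t() * Xw;
  return 0.5 * (S + S.t());
}

// Fused sliding-window loop: weighted covariance -> glasso precision ->
// implied covariance -> correlation -> Fisher z, warm-starting each window's
// glasso at the previous window's solution. Returns W x P matrix with pairs
// ordered (i,j), i<j, j inner loop.
// [[Rcpp::export]]
arma::mat windowed_zfc_cpp(const arma::mat& X, const arma::ivec& starts,
                           const arma::vec& taper, double lambda,
                           int max_iter, double tol) {
  const int C = X.n_cols;
  const int W = starts.n_elem;
  const int P = C * (C - 1) / 2;
  const double rmax = 1.0 - 1e-7;
  mat Z(W, P);
  Rcpp::NumericMatrix warm;
  bool have_warm = false;

  for (int w = 0; w < W; ++w) {
    mat S = weighted_cov_cpp(X, starts[w], taper);
    Rcpp::List fit = glasso_cpp(
      S, lambda, max_iter, tol,
      have_warm ? Rcpp::Nullable<Rcpp::NumericMatrix>(warm)
                : Rcpp::Nullable<Rcpp::NumericMatrix>(R_NilValue));
    mat Theta = fit["theta"];
    mat Sigma;
    bool ok = inv_sympd(Sigma, Theta);
    if (!ok) Sigma = pinv(Theta);
    warm = Rcpp::wrap(Rcpp::as<Rcpp::NumericMatrix>(fit["w"]));
    have_warm = true;
    vec d = 1.0 / sqrt(Sigma.diag());
    int q = 0;
    for (int i = 0; i < C - 1; ++i) {
      for (int j = i + 1; j < C; ++j, ++q) {
        double r = Sigma(i, j) * d[i] * d[j];
        if (r > rmax) r = rmax;
        if (r < -rmax) r = -rmax;
        Z(w, q) = std::atanh(r);
      }
    }
  }
  return Z;
}
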