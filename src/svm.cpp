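// Dual solver for the C-SVC with a linear kernel (hinge loss, L2 penalty),
// used by train_linear_decoder() and train_ensemble_decoder().  The dual QP
//
//   min_a  1/2 a' Q a - e' a ,  0 <= a_i <= C ,  y' a = 0 ,  Q_ij = y_i y_j K_ij
//
// is solved by sequential minimal optimization with maximal-violating-pair
// working-set selection.  Problem sizes here are tiny (tens of samples after
// balanced subsampling), so the full Gram matrix is precomputed; the ensemble
// entry point reuses one Gram matrix of the pooled training set across all
// subsamples.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Returns the intercept b (decision value = w'x + b); alpha is filled in.
static double smo_csvc(const mat &K, const vec &y, const double C,
                       const double eps, const int max_iter, vec &alpha) {
  const int n = K.n_rows;
  const double TAU = 1e-12;
  alpha.zeros(n);
  vec G(n);
  G.fill(-1.0); // gradient of the dual objective at alpha = 0

  int iter = 0;
  double Gmax = 0.0, Gmin = 0.0;
  while (iter < max_iter) {
    int i = -1, j = -1;
    Gmax = -datum::inf;
    Gmin = datum::inf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      if ((y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0)) {
        if (v >= Gmax) { Gmax = v; i = t; }
      }
      if ((y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C)) {
        if (v <= Gmin) { Gmin = v; j = t; }
      }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = TAU;
    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = y[i] * (alpha[i] - ai_old);
    const double daj = y[j] * (alpha[j] - aj_old);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (K(t, i) * dai + K(t, j) * daj);
    ++iter;
  }

  // Intercept from the KKT conditions: average of y_t - w'x_t over free
  // support vectors; midpoint of the feasibility bounds if none are free.
  double ub = datum::inf, lb = -datum::inf, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] < 0) ub = std::min(ub, yG);
      else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] > 0) ub = std::min(ub, yG);
      else lb = std::max(lb, yG);
    } else {
      ++n_free;
      sum_free += yG;
    }
  }
  const double rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;
  return -rho;
}

//' @noRd
// [[Rcpp::export(name = ".svc_linear_fit")]]
Rcpp::List svc_linear_fit(const arma::mat &X, const arma::vec &y,
                          const double cost, const double eps = 1e-6,
                          const int max_iter = 1000000) {
  const mat K = X * X.t();
  vec alpha;
  const double b = smo_csvc(K, y, cost, eps, max_iter, alpha);
  const vec w = X.t() * (alpha % y);
  return Rcpp::List::create(Rcpp::Named("weights") = w,
                            Rcpp::Named("bias") = b,
                            Rcpp::Named("alpha") = alpha);
}

//' @noRd
// [[Rcpp::export(name = ".svc_ensemble_fit")]]
Rcpp::List svc_ensemble_fit(const arma::mat &X, const arma::vec &y,
                            const arma::umat &subset_idx, const double cost,
                            const double eps = 1e-6,
                            const int max_iter = 1000000) {
  // subset_idx: one column per ensemble member, 1-based row indices into X.
  const mat K = X * X.t();
  const int n_subsets = subset_idx.n_cols;
  vec wbar(X.n_cols, fill::zeros);
  double bbar = 0.0;
  for (int s = 0; s < n_subsets; ++s) {
    const uvec idx = subset_idx.col(s) - 1;
    const mat Ks = K.submat(idx, idx);
    const vec ys = y.elem(idx);
    vec alpha;
    const double b = smo_csvc(Ks, ys, cost, eps, max_iter, alpha);
    wbar += X.rows(idx).t() * (alpha % ys);
    bbar += b;
  }
  wbar /= n_subsets;
  bbar /= n_subsets;
  return Rcpp::List::create(Rcpp::Named("weights") = wbar,
                            Rcpp::Named("bias") = bbar);
}
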