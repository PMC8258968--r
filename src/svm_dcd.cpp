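#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized hinge-loss (L1) linear SVM:
//   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// solved in the dual with box constraints 0 <= alpha_i <= C. A bias term, if
// wanted, is an augmented constant feature column in X. Coordinates are
// visited in a randomly permuted order each epoch (xorshift PRNG, seeded for
// reproducibility); convergence is declared when the projected-gradient
// spread falls below tol.
// [[Rcpp::export]]
NumericVector svm_dcd_cpp(NumericMatrix X, IntegerVector y, double C,
                          double tol = 1e-4, int max_epochs = 1000,
                          int seed = 1) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (y.size() != n) stop("label length mismatch");
  std::vector<double> alpha(n, 0.0), qii(n), w(p, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) { const double v = X(i, j); s += v * v; }
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned int state = seed ? (unsigned int)seed : 0x9e3779b9u;
  auto next_rand = [&state]() {
    state ^= state << 13; state ^= state >> 17; state ^= state << 5;
    return state;
  };
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {
      const int j = next_rand() % (i + 1);
      std::swap(idx[i], idx[j]);
    }
    double pg_max = -1e300, pg_min = 1e300;
    for (int k = 0; k < n; ++k) {
      const int i = idx[k];
      if (qii[i] <= 0.0) continue;
      double g = 0.0;
      for (int j = 0; j < p; ++j) g += w[j] * X(i, j);
      g = g * y[i] - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      pg_max = std::max(pg_max, pg);
      pg_min = std::min(pg_min, pg);
      if (std::fabs(pg) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        a_new = std::min(std::max(a_new, 0.0), C);
        if (a_new != a_old) {
          const double d = (a_new - a_old) * y[i];
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
          alpha[i] = a_new;
        }
      }
    }
    if (pg_max - pg_min < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
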