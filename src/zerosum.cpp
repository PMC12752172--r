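#include <Rcpp.h>
using namespace Rcpp;

// Elastic net under the zero-sum constraint sum(beta) = 0, solved by
// pairwise coordinate descent: each update moves a pair (beta_j + delta,
// beta_k - delta), which preserves the constraint exactly at every step
// and keeps lasso zeros exact (the one-dimensional subproblem is piecewise
// quadratic with kinks at -beta_j and beta_k). Weighted squared-error
// loss; weights are normalised internally. Residual correlations are
// tracked in coefficient space through the Gram matrix, so a pair update
// costs O(p).
// [[Rcpp::export]]
List zerosum_enet_cpp(NumericMatrix Z, NumericVector y, double lambda,
                      double alpha_mix, NumericVector w,
                      NumericVector beta_init, double beta0_init,
                      double tol, int max_sweeps) {
  const int n = Z.nrow(), p = Z.ncol();
  std::vector<double> wn(n), beta(p), r(n);
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];
  for (int i = 0; i < n; ++i) wn[i] = w[i] / wsum;
  for (int k = 0; k < p; ++k) beta[k] = beta_init[k];
  double beta0 = beta0_init;
  for (int i = 0; i < n; ++i) {
    double eta = beta0;
    for (int k = 0; k < p; ++k) eta += Z(i, k) * beta[k];
    r[i] = y[i] - eta;
  }
  const double lam1 = lambda * alpha_mix, lam2 = lambda * (1.0 - alpha_mix);

  // weighted Gram matrix and weighted column means
  std::vector<double> G(p * p), zmean(p), v(p);
  for (int j = 0; j < p; ++j) {
    double zm = 0.0;
    for (int i = 0; i < n; ++i) zm += wn[i] * Z(i, j);
    zmean[j] = zm;
  }
  for (int j = 0; j < p; ++j)
    for (int k = j; k < p; ++k) {
      double a = 0.0;
      for (int i = 0; i < n; ++i) a += wn[i] * Z(i, j) * Z(i, k);
      G[j * p + k] = G[k * p + j] = a;
    }
  double rmean = 0.0;
  for (int j = 0; j < p; ++j) {
    double a = 0.0;
    for (int i = 0; i < n; ++i) a += wn[i] * Z(i, j) * r[i];
    v[j] = a;                            // v = Z' W r / sum(w)
  }
  for (int i = 0; i < n; ++i) rmean += wn[i] * r[i];

  auto obj1d = [&](double A, double C, double bj, double bk,
                   double delta) {
    return 0.5 * A * delta * delta - C * delta +
           lam1 * (std::fabs(bj + delta) + std::fabs(bk - delta));
  };

  for (int sweep_i = 0; sweep_i < max_sweeps; ++sweep_i) {
    double delta_max = 0.0;
    for (int j = 0; j < p - 1; ++j) {
      for (int k = j + 1; k < p; ++k) {
        double a = G[j * p + j] + G[k * p + k] - 2.0 * G[j * p + k];
        double c = v[j] - v[k];
        double A = a + 2.0 * lam2;
        if (A <= 0.0) continue;
        double C = c - lam2 * (beta[j] - beta[k]);
        double cand[5] = { (C + 2.0 * lam1) / A, C / A,
                           (C - 2.0 * lam1) / A, -beta[j], beta[k] };
        double best = 0.0, bestval = obj1d(A, C, beta[j], beta[k], 0.0);
        for (int t = 0; t < 5; ++t) {
          double val = obj1d(A, C, beta[j], beta[k], cand[t]);
          if (val < bestval - 1e-15) { bestval = val; best = cand[t]; }
        }
        if (best != 0.0) {
          for (int m = 0; m < p; ++m)
            v[m] -= (G[m * p + j] - G[m * p + k]) * best;
          rmean -= (zmean[j] - zmean[k]) * best;
          beta[j] += best;
          beta[k] -= best;
          double ad = std::fabs(best);
          if (ad > delta_max) delta_max = ad;
        }
      }
    }
    // intercept absorbs the weighted residual mean
    double db0 = rmean;
    beta0 += db0;
    for (int j = 0; j < p; ++j) v[j] -= db0 * zmean[j];
    rmean = 0.0;
    if (delta_max < tol && std::fabs(db0) < tol) break;
  }
  double s = 0.0;
  for (int k = 0; k < p; ++k) s += beta[k];
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["beta0"] = beta0, _["sum_beta"] = s);
}
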