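#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// C-SVM with RBF kernel trained by sequential minimal optimization (SMO,
// Platt-style with the |E1 - E2| second-choice heuristic).  Deterministic:
// no random index selection, so identical inputs give identical models.
// Sized for the desk-scale problems this package trains on (n in the
// hundreds); the full kernel matrix is precomputed.

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    double v = X(i, k) - X(j, k);
    s += v * v;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List svm_smo_train_cpp(NumericMatrix X, NumericVector y, double C,
                       double gamma, double tol = 1e-3,
                       int max_passes = 5, int max_sweeps = 2000) {
  int n = X.nrow();
  std::vector<std::vector<double> > K(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[i][j] = K[j][i] = rbf(X, i, j, gamma);

  std::vector<double> alpha(n, 0.0);
  double b = 0.0;
  std::vector<double> E(n);
  for (int i = 0; i < n; ++i) E[i] = -y[i]; // f(x)=0 initially

  int passes = 0, sweeps = 0;
  while (passes < max_passes && sweeps < max_sweeps) {
    ++sweeps;
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = E[i];
      double ri = Ei * y[i];
      if ((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0)) {
        // second choice: maximize |Ei - Ej|
        int j = -1;
        double best = -1.0;
        for (int t = 0; t < n; ++t) {
          if (t == i) continue;
          double v = std::fabs(Ei - E[t]);
          if (v > best) { best = v; j = t; }
        }
        if (j < 0) continue;
        double ai = alpha[i], aj = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj - ai);
          H = std::min(C, C + aj - ai);
        } else {
          L = std::max(0.0, ai + aj - C);
          H = std::min(C, ai + aj);
        }
        if (L >= H) continue;
        double eta = 2.0 * K[i][j] - K[i][i] - K[j][j];
        if (eta >= 0) continue;
        double ajNew = aj - y[j] * (Ei - E[j]) / eta;
        if (ajNew > H) ajNew = H;
        else if (ajNew < L) ajNew = L;
        if (std::fabs(ajNew - aj) < 1e-7) continue;
        double aiNew = ai + y[i] * y[j] * (aj - ajNew);
        double b1 = b - Ei - y[i] * (aiNew - ai) * K[i][i]
          - y[j] * (ajNew - aj) * K[i][j];
        double b2 = b - E[j] - y[i] * (aiNew - ai) * K[i][j]
          - y[j] * (ajNew - aj) * K[j][j];
        double bNew;
        if (aiNew > 0 && aiNew < C) bNew = b1;
        else if (ajNew > 0 && ajNew < C) bNew = b2;
        else bNew = 0.5 * (b1 + b2);
        double dAi = (aiNew - ai) * y[i], dAj = (ajNew - aj) * y[j];
        for (int t = 0; t < n; ++t)
          E[t] += dAi * K[i][t] + dAj * K[j][t] + (bNew - b);
        alpha[i] = aiNew;
        alpha[j] = ajNew;
        b = bNew;
        ++changed;
      }
    }
    if (changed == 0) ++passes;
    else passes = 0;
  }

  // collect support vectors
  std::vector<int> sv;
  for (int i = 0; i < n; ++i) if (alpha[i] > 1e-8) sv.push_back(i);
  int m = (int) sv.size();
  NumericMatrix SV(m, X.ncol());
  NumericVector coef(m);
  for (int s = 0; s < m; ++s) {
    int i = sv[s];
    coef[s] = alpha[i] * y[i];
    for (int k = 0; k < X.ncol(); ++k) SV(s, k) = X(i, k);
  }
  return List::create(_["sv"] = SV, _["coef"] = coef, _["b"] = b,
                      _["gamma"] = gamma, _["C"] = C,
                      _["n_sv"] = m);
}

// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix SV, NumericVector coef,
                               double b, double gamma, NumericMatrix X) {
  int n = X.nrow(), m = SV.nrow(), d = X.ncol();
  NumericVector f(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      double q = 0.0;
      for (int k = 0; k < d; ++k) {
        double v = X(i, k) - SV(j, k);
        q += v * v;
      }
      s += coef[j] * std::exp(-gamma * q);
    }
    f[i] = s + b;
  }
  return f;
}
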