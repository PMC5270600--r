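// Precomputed-kernel C-SVC via SMO with maximal-violating-pair working-set
// selection (LIBSVM's WSS1). Kernels arising from a pseudo-distance need not
// be positive semidefinite; the usual tau guard on the second-order step
// keeps the update well defined, and an iteration cap guarantees
// termination.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void smo_core(const double* K, int n, const int* y, double C,
                     double tol, int max_iter,
                     std::vector<double>& alpha, double& b, int& iters) {
  std::vector<double> grad(n, -1.0);  // grad of 0.5 a'Qa - e'a, Q=yy'K
  alpha.assign(n, 0.0);
  int it = 0;
  while (it < max_iter) {
    ++it;
    double Gmax = -1e300, Gmin = 1e300;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      double v = -y[t] * grad[t];
      if (up  && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) break;
    double eta = K[i * n + i] + K[j * n + j] - 2.0 * K[i * n + j];
    if (eta <= 0) eta = 1e-12;
    double Ei = y[i] * grad[i];          // f0(x_i) - y_i
    double Ej = y[j] * grad[j];
    double ai_old = alpha[i], aj_old = alpha[j];
    double s = (double)(y[i] * y[j]);
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    double aj = aj_old + y[j] * (Ei - Ej) / eta;
    if (aj < L) aj = L;
    if (aj > H) aj = H;
    double ai = ai_old + s * (aj_old - aj);
    double dai = ai - ai_old, daj = aj - aj_old;
    if (std::fabs(dai) < 1e-14 && std::fabs(daj) < 1e-14) break;
    alpha[i] = ai; alpha[j] = aj;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K[t * n + i] * dai + y[j] * K[t * n + j] * daj);
  }
  iters = it;
  double sum = 0.0; int cnt = 0;
  double Gmax = -1e300, Gmin = 1e300;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * grad[t];
    bool up  = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
    bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { sum += v; ++cnt; }
    if (up)  Gmax = std::max(Gmax, v);
    if (low) Gmin = std::min(Gmin, v);
  }
  b = cnt ? sum / cnt : 0.5 * (Gmax + Gmin);
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix K, IntegerVector y, double C,
               double tol = 1e-3, int max_iter = 100000) {
  int n = K.nrow();
  std::vector<double> alpha;
  double b; int iters;
  smo_core(REAL(K), n, INTEGER(y), C, tol, max_iter, alpha, b, iters);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iters);
}

// Cross-validated accuracy over the full (gamma, C) grid. D is the training
// pseudo-distance matrix; fold holds 1-based fold ids per sample. Returns
// accuracy with rows = gammas, cols = Cs.
// [[Rcpp::export(name = ".svm_grid_cv")]]
NumericMatrix svm_grid_cv(NumericMatrix D, IntegerVector y,
                          NumericVector gammas, NumericVector Cs,
                          IntegerVector fold, double tol = 1e-3,
                          int max_iter = 100000) {
  int n = D.nrow(), ng = gammas.size(), nc = Cs.size();
  int nfold = 0;
  for (int t = 0; t < n; ++t) nfold = std::max(nfold, fold[t]);
  NumericMatrix acc(ng, nc);
  std::vector<double> K(n * n);
  std::vector<int> tr_idx, te_idx;
  std::vector<double> subK;
  std::vector<int> suby;
  std::vector<double> alpha;
  for (int g = 0; g < ng; ++g) {
    double gamma = gammas[g];
    for (int t = 0; t < n * n; ++t) {
      double d = D[t];
      K[t] = std::exp(-d * d / gamma);
    }
    std::vector<int> correct(nc, 0), total(nc, 0);
    for (int f = 1; f <= nfold; ++f) {
      tr_idx.clear(); te_idx.clear();
      for (int t = 0; t < n; ++t)
        (fold[t] == f ? te_idx : tr_idx).push_back(t);
      int ntr = tr_idx.size(), nte = te_idx.size();
      if (ntr == 0 || nte == 0) continue;
      // folds containing a single training class: majority vote fallback
      int npos = 0;
      for (int t = 0; t < ntr; ++t) if (y[tr_idx[t]] == 1) ++npos;
      if (npos == 0 || npos == ntr) {
        int maj = (2 * npos > ntr) ? 1 : -1;
        for (int c = 0; c < nc; ++c)
          for (int t = 0; t < nte; ++t) {
            ++total[c];
            if (y[te_idx[t]] == maj) ++correct[c];
          }
        continue;
      }
      subK.assign((size_t)ntr * ntr, 0.0);
      suby.assign(ntr, 0);
      for (int r = 0; r < ntr; ++r) {
        suby[r] = y[tr_idx[r]];
        for (int c2 = 0; c2 < ntr; ++c2)
          subK[(size_t)c2 * ntr + r] = K[(size_t)tr_idx[c2] * n + tr_idx[r]];
      }
      for (int c = 0; c < nc; ++c) {
        double b; int iters;
        smo_core(subK.data(), ntr, suby.data(), Cs[c], tol, max_iter,
                 alpha, b, iters);
        for (int t = 0; t < nte; ++t) {
          double score = b;
          for (int r = 0; r < ntr; ++r)
            score += alpha[r] * suby[r] * K[(size_t)te_idx[t] * n + tr_idx[r]];
          ++total[c];
          if ((score > 0 ? 1 : -1) == y[te_idx[t]]) ++correct[c];
        }
      }
    }
    for (int c = 0; c < nc; ++c)
      acc(g, c) = total[c] ? (double)correct[c] / total[c] : NA_REAL;
  }
  return acc;
}
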