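#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Squared Euclidean distance between rows a (of X) and b (of Y).
static inline double sqdist(const NumericMatrix &X, int a,
                            const NumericMatrix &Y, int b) {
  const int d = X.ncol();
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    const double diff = X(a, k) - Y(b, k);
    s += diff * diff;
  }
  return s;
}

// [[Rcpp::export(name = ".rbf_cross_kernel")]]
NumericMatrix rbf_cross_kernel(NumericMatrix X, NumericMatrix Y, double gamma) {
  const int n = X.nrow(), m = Y.nrow();
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      K(i, j) = std::exp(-gamma * sqdist(X, i, Y, j));
  return K;
}

// Solve the C-SVC dual
//   min 1/2 a'Qa - e'a,  0 <= a_i <= C,  y'a = 0,  Q_ij = y_i y_j K_ij
// by sequential minimal optimization with second-order working-set
// selection.  F_t tracks sum_s a_s y_s K_st (decision value without the
// intercept); the violation measures are y_t - F_t over the up/low sets.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix X, NumericVector y, double C, double gamma,
               double eps, int max_iter) {
  const int n = X.nrow();
  if (n < 2) stop("need at least 2 training points");

  // dense kernel matrix; training pairs in this package are small
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = std::exp(-gamma * sqdist(X, i, X, j));
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), F(n, 0.0);
  const double tau = 1e-12;
  int iter = 0;

  for (; iter < max_iter; ++iter) {
    // i: most violating index in the "up" set
    int i = -1;
    double Gmax = -INFINITY;
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      if (!up) continue;
      const double v = y[t] - F[t];
      if (v > Gmax) { Gmax = v; i = t; }
    }
    if (i < 0) break;

    // j: second-order gain among sufficiently violating "low" indices
    int j = -1;
    double Gmin = INFINITY, best = 0.0;
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!low) continue;
      const double v = y[t] - F[t];
      if (v < Gmin) Gmin = v;
      const double b_t = Gmax - v;
      if (b_t > eps) {
        double a_t = K[(size_t)i * n + i] + K[(size_t)t * n + t] -
                     2.0 * K[(size_t)i * n + t];
        if (a_t <= 0) a_t = tau;
        const double gain = -(b_t * b_t) / a_t;
        if (gain < best) { best = gain; j = t; }
      }
    }
    if (j < 0 || Gmax - Gmin < eps) break;

    // analytic two-variable update (pair i, j)
    const double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
                 Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = tau;
    const double Ei = F[i] - y[i], Ej = F[j] - y[j];

    const double ai_old = alpha[i], aj_old = alpha[j];
    const double step = y[j] * (Ei - Ej) / eta;
    double ai, aj;
    if (y[i] * y[j] < 0) {
      // ai - aj invariant; both alphas move by the same amount
      const double diff = ai_old - aj_old;
      ai = ai_old + step;
      aj = aj_old + step;
      if (diff > 0) {
        if (aj < 0) { aj = 0; ai = diff; }
      } else {
        if (ai < 0) { ai = 0; aj = -diff; }
      }
      if (diff > 0) {
        if (ai > C) { ai = C; aj = C - diff; }
      } else {
        if (aj > C) { aj = C; ai = C + diff; }
      }
    } else {
      // ai + aj invariant; alphas move in opposite directions
      const double sum = ai_old + aj_old;
      ai = ai_old - step;
      aj = aj_old + step;
      if (sum > C) {
        if (ai > C) { ai = C; aj = sum - C; }
        else if (aj > C) { aj = C; ai = sum - C; }
      } else {
        if (aj < 0) { aj = 0; ai = sum; }
        else if (ai < 0) { ai = 0; aj = sum; }
      }
    }
    const double dai = ai - ai_old, daj = aj - aj_old;
    if (dai == 0.0 && daj == 0.0) break;  // no representable progress
    alpha[i] = ai;
    alpha[j] = aj;

    for (int t = 0; t < n; ++t)
      F[t] += dai * y[i] * K[(size_t)i * n + t] +
              daj * y[j] * K[(size_t)j * n + t];
  }

  // intercept: midpoint of the optimal-b interval [max over up, min over low]
  double m = -INFINITY, M = INFINITY;
  for (int t = 0; t < n; ++t) {
    const double v = y[t] - F[t];
    const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (up && v > m) m = v;
    if (low && v < M) M = v;
  }
  double b = 0.0;
  if (std::isfinite(m) && std::isfinite(M)) b = (m + M) / 2.0;
  else if (std::isfinite(m)) b = m;
  else if (std::isfinite(M)) b = M;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
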