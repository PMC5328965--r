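#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin C-SVC dual solver for the Gaussian RBF kernel, by sequential
// minimal optimization with maximal-violating-pair working-set selection
// (Keerthi et al.'s SMO modification). Problems here are tiny (n <= a few
// hundred), so the full kernel matrix is formed up front.
//
// Dual: max sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij
//       s.t. 0 <= alpha_i <= C, sum_i alpha_i y_i = 0
// Decision: f(x) = sum_i alpha_i y_i k(x_i, x) + b, prediction sign(f).
// [[Rcpp::export(name = ".smoTrain")]]
List smoTrain(NumericMatrix X, NumericVector y, double C, double gamma,
              double tol = 1e-8, int maxIter = 2000000) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("labels must match the number of rows");
  if (C <= 0) stop("C must be > 0");

  // RBF kernel matrix
  std::vector<double> K((size_t)n * n);
  std::vector<double> sq(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int f = 0; f < p; ++f) s += X(i, f) * X(i, f);
    sq[i] = s;
  }
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double dot = 0.0;
      for (int f = 0; f < p; ++f) dot += X(i, f) * X(j, f);
      double d2 = sq[i] + sq[j] - 2.0 * dot;
      double v = std::exp(-gamma * (d2 > 0 ? d2 : 0.0));
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0);
  std::vector<double> fcache(n, 0.0);  // f_i = sum_t alpha_t y_t K_ti (no b)
  double m = 0.0, M = 0.0;
  int iter = 0;
  for (; iter < maxIter; ++iter) {
    // i: argmax over I_up of -E_t, j: argmin over I_low of -E_t,
    // where E_t = f_t - y_t
    int ii = -1, jj = -1;
    m = -HUGE_VAL; M = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - fcache[t];  // -E_t
      const bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > m) { m = v; ii = t; }
      if (low && v < M) { M = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || m - M < tol) break;

    const double Ei = fcache[ii] - y[ii], Ej = fcache[jj] - y[jj];
    const double ai = alpha[ii], aj = alpha[jj];
    double L, H;
    if (y[ii] != y[jj]) {
      L = std::max(0.0, aj - ai);
      H = std::min(C, C + aj - ai);
    } else {
      L = std::max(0.0, ai + aj - C);
      H = std::min(C, ai + aj);
    }
    if (H - L < 1e-15) break;  // degenerate box; cannot occur analytically
    double eta = K[(size_t)ii * n + ii] + K[(size_t)jj * n + jj]
               - 2.0 * K[(size_t)ii * n + jj];
    if (eta < 1e-12) eta = 1e-12;
    double ajNew = aj + y[jj] * (Ei - Ej) / eta;
    if (ajNew < L) ajNew = L; else if (ajNew > H) ajNew = H;
    const double dj = ajNew - aj;
    if (std::fabs(dj) < 1e-15) break;  // no numerical progress possible
    const double di = -y[ii] * y[jj] * dj;
    alpha[ii] = ai + di;
    alpha[jj] = ajNew;
    const double ci = di * y[ii], cj = dj * y[jj];
    const double* Ki = &K[(size_t)ii * n];
    const double* Kj = &K[(size_t)jj * n];
    for (int t = 0; t < n; ++t) fcache[t] += ci * Ki[t] + cj * Kj[t];
  }
  const double b = (m + M) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < maxIter);
}
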