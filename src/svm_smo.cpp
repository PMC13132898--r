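// C-support vector classification via sequential minimal optimisation with
// maximal-violating-pair working-set selection (the classical decomposition
// scheme). Kernels: linear, RBF, polynomial (degree 3). Problem sizes here
// are tiny (around a hundred rows per training fold), so the full kernel
// matrix is materialised.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static double kern(const NumericMatrix &X, int i, const NumericMatrix &Z,
                   int j, int type, double gamma, double coef0) {
  const int p = X.ncol();
  if (type == 1) { // rbf
    double s = 0.0;
    for (int k = 0; k < p; ++k) {
      double d = X(i, k) - Z(j, k);
      s += d * d;
    }
    return std::exp(-gamma * s);
  }
  double dot = 0.0;
  for (int k = 0; k < p; ++k) dot += X(i, k) * Z(j, k);
  if (type == 0) return dot;                       // linear
  double b = gamma * dot + coef0;                  // poly, degree 3
  return b * b * b;
}

static int kernel_code(const std::string &kernel) {
  if (kernel == "linear") return 0;
  if (kernel == "rbf") return 1;
  if (kernel == "poly") return 2;
  stop("unknown kernel '%s'", kernel.c_str());
  return -1;
}

// [[Rcpp::export]]
List svm_train_cpp(NumericMatrix X, NumericVector y, double C,
                   std::string kernel, double gamma, double coef0,
                   double tol = 1e-3, int max_pair_updates = 200000) {
  const int n = X.nrow();
  const int ktype = kernel_code(kernel);
  // kernel matrix
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[(size_t)i * n + j] = K[(size_t)j * n + i] =
          kern(X, i, X, j, ktype, gamma, coef0);

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G_i = y_i u_i - 1
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  while (iter++ < max_pair_updates) {
    int i = -1, j = -1;
    m_up = -1e300;
    m_low = 1e300;
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) break;

    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                 2.0 * K[(size_t)i * n + j];
    if (eta < 1e-12) eta = 1e-12;
    double t_step = (m_up - m_low) / eta; // unclipped step along (y_i, -y_j)
    // box constraints on alpha_i + y_i t and alpha_j - y_j t
    double t_max = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double t_max2 = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (t_step > t_max) t_step = t_max;
    if (t_step > t_max2) t_step = t_max2;
    if (t_step <= 0) break;
    alpha[i] += y[i] * t_step;
    alpha[j] -= y[j] * t_step;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * t_step * (K[(size_t)i * n + t] - K[(size_t)j * n + t]);
    }
  }

  // bias: average of y_i - u_i over free support vectors, else gap midpoint
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b += -y[t] * G[t];
      ++nfree;
    }
  }
  b = (nfree > 0) ? b / nfree : 0.5 * (m_up + m_low);

  // compress to support vectors
  std::vector<int> sv;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-12) sv.push_back(t);
  NumericMatrix SV(sv.size(), X.ncol());
  NumericVector coefs(sv.size());
  for (size_t s = 0; s < sv.size(); ++s) {
    for (int k = 0; k < X.ncol(); ++k) SV(s, k) = X(sv[s], k);
    coefs[s] = alpha[sv[s]] * y[sv[s]];
  }
  return List::create(_["sv"] = SV, _["coefs"] = coefs, _["b"] = b,
                      _["kernel"] = kernel, _["gamma"] = gamma,
                      _["coef0"] = coef0,
                      _["converged"] = (iter < max_pair_updates));
}

// [[Rcpp::export]]
NumericVector svm_decision_cpp(List model, NumericMatrix X) {
  NumericMatrix SV = model["sv"];
  NumericVector coefs = model["coefs"];
  const double b = as<double>(model["b"]);
  const int ktype = kernel_code(as<std::string>(model["kernel"]));
  const double gamma = as<double>(model["gamma"]);
  const double coef0 = as<double>(model["coef0"]);
  const int n = X.nrow();
  NumericVector out(n, b);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int sIdx = 0; sIdx < SV.nrow(); ++sIdx) {
      s += coefs[sIdx] * kern(X, i, SV, sIdx, ktype, gamma, coef0);
    }
    out[i] += s;
  }
  return out;
}
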