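#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// exp(-t) for t in [0, 45), accurate to ~1 ulp: range reduction by log 2 and
// a degree-12 Taylor polynomial on |r| <= log(2)/2 (max term ~2e-16). Inlined
// so the hot pair loop pipelines instead of calling libm.
static inline double exp_neg(double t) {
  const double log2e = 1.4426950408889634074;
  const double ln2_hi = 6.93147180369123816490e-01;
  const double ln2_lo = 1.90821492927058770002e-10;
  double z = -t * log2e;                  // in [-65, 0]
  int ik = (int)(z - 0.5);                // round to nearest (z <= 0)
  if (z - ik > 0.5) ++ik;
  double k = (double)ik;
  double r = (-t - k * ln2_hi) - k * ln2_lo;
  double p = 1.0 + r * (1.0 + r * (1.0 / 2 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040 +
             r * (1.0 / 40320 + r * (1.0 / 362880 + r * (1.0 / 3628800 +
             r * (1.0 / 39916800 + r / 479001600)))))))))));
  // scale by 2^ik via direct exponent-field construction (ik in [-65, 1])
  union { double d; unsigned long long u; } two_k;
  two_k.u = (unsigned long long)(1023 + ik) << 52;
  return p * two_k.d;
}

// Template pair statistics shared by sample entropy and fuzzy entropy.
//
// Templates are the N - m overlapping subsequences of length m + 1 (so each
// template supports both the length-m and the length-(m+1) comparison),
// compared under Chebyshev distance; self-matches excluded (pairs i < j
// only). Returns the counts of matching pairs (d <= r) at lengths m and m+1
// and the fuzzy membership sums exp(-(d/r)^2) at both lengths.
//
// Pairs whose first-coordinate difference exceeds sqrt(45) r contribute
// nothing (no match, membership < 3e-20, i.e. below double rounding noise of
// the accumulated sums), so templates are sorted by first coordinate and
// each template is compared only against its window of near neighbours.
// [[Rcpp::export]]
NumericVector pair_match_stats(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m; // number of length-(m+1)-capable templates
  double a_m = 0.0, a_m1 = 0.0, c_m = 0.0, c_m1 = 0.0;
  if (nt < 2) {
    return NumericVector::create(
        _["A_m"] = 0.0, _["A_m1"] = 0.0, _["C_m"] = 0.0, _["C_m1"] = 0.0,
        _["pairs"] = 0.0);
  }
  const double *px = REAL(x);
  const double span = (r > 0.0) ? std::sqrt(45.0) * r : 0.0;
  const double inv_r2 = (r > 0.0) ? 1.0 / (r * r) : 0.0;

  std::vector<int> ord(nt);
  for (int i = 0; i < nt; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return px[a] < px[b]; });
  // copy template coordinates into sorted-order contiguous arrays so the
  // inner loop streams memory instead of gathering
  std::vector<double> coord((size_t)(m + 1) * nt);
  for (int k = 0; k <= m; ++k) {
    double *ck = &coord[(size_t)k * nt];
    for (int a = 0; a < nt; ++a) ck[a] = px[ord[a] + k];
  }
  const double *c0 = &coord[0];

  for (int a = 0; a < nt - 1; ++a) {
    const double xi = c0[a];
    for (int b = a + 1; b < nt; ++b) {
      if (c0[b] - xi > span) break; // sorted: no further contributions
      double dm = c0[b] - xi; // first coordinate, nonnegative by sort
      for (int k = 1; k < m; ++k) {
        const double *ck = &coord[(size_t)k * nt];
        double d = std::fabs(ck[a] - ck[b]);
        if (d > dm) dm = d;
      }
      double dm1 = dm;
      {
        const double *cm = &coord[(size_t)m * nt];
        double d = std::fabs(cm[a] - cm[b]);
        if (d > dm1) dm1 = d;
      }
      if (dm <= r) a_m += 1.0;
      if (dm1 <= r) a_m1 += 1.0;
      if (r > 0.0) {
        double t = dm * dm * inv_r2;
        if (t < 45.0) c_m += exp_neg(t);
        t = dm1 * dm1 * inv_r2;
        if (t < 45.0) c_m1 += exp_neg(t);
      } else {
        if (dm == 0.0) c_m += 1.0;
        if (dm1 == 0.0) c_m1 += 1.0;
      }
    }
  }
  double pairs = 0.5 * (double)nt * (double)(nt - 1);
  return NumericVector::create(
      _["A_m"] = a_m, _["A_m1"] = a_m1, _["C_m"] = c_m, _["C_m1"] = c_m1,
      _["pairs"] = pairs);
}
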