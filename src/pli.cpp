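#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Phase Lag Index for every unordered channel pair.
//
// `phase` is a samples x channels matrix of instantaneous phases. For a pair
// (i, j), sign(wrap(phi_i - phi_j)) equals sign(sin(phi_i - phi_j)) away
// from the measure-zero set phi_i - phi_j = pi, and
// sin(phi_i - phi_j) = sin(phi_i) cos(phi_j) - cos(phi_i) sin(phi_j),
// so the sums run on precomputed sin/cos tables. Identical channels give an
// exact elementwise zero, hence PLI exactly 0 (sign(0) = 0 convention).
//
// Returns the column-major upper triangle, i.e. the same edge order as
// m[upper.tri(m)] in R.
// [[Rcpp::export(name = ".pliUpperCpp")]]
NumericVector pliUpper(const NumericMatrix& phase) {
  const int n = phase.nrow();
  const int C = phase.ncol();
  if (C < 2) stop("need at least two channels");
  if (n < 1) stop("need at least one sample");

  std::vector<double> s(static_cast<size_t>(n) * C),
                      c(static_cast<size_t>(n) * C);
  for (int j = 0; j < C; ++j) {
    const double* p = &phase(0, j);
    double* sj = &s[static_cast<size_t>(j) * n];
    double* cj = &c[static_cast<size_t>(j) * n];
    for (int t = 0; t < n; ++t) {
      sj[t] = std::sin(p[t]);
      cj[t] = std::cos(p[t]);
    }
  }

  NumericVector out(C * (C - 1) / 2);
  int k = 0;
  for (int j = 1; j < C; ++j) {
    const double* sjv = &s[static_cast<size_t>(j) * n];
    const double* cjv = &c[static_cast<size_t>(j) * n];
    for (int i = 0; i < j; ++i, ++k) {
      const double* siv = &s[static_cast<size_t>(i) * n];
      const double* civ = &c[static_cast<size_t>(i) * n];
      long long acc = 0;
      for (int t = 0; t < n; ++t) {
        const double x = siv[t] * cjv[t] - civ[t] * sjv[t];
        acc += (x > 0.0) - (x < 0.0);
      }
      out[k] = std::fabs(static_cast<double>(acc) / n);
    }
  }
  return out;
}
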