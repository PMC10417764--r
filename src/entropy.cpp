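#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev (max-norm) distance between templates x[i..i+m-1], x[j..j+m-1]
static inline bool cheb_match(const double* x, int i, int j, int m, double r) {
  for (int k = 0; k < m; ++k) {
    double d = x[i + k] - x[j + k];
    if (d > r || d < -r) return false;
  }
  return true;
}

// phi^m(r) for approximate entropy: mean over i of log(C_i), where C_i is
// the proportion of templates within Chebyshev distance r, self-matches
// included. Templates of length m; there are n - m + 1 of them.
// [[Rcpp::export]]
double apen_phi(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m + 1;
  if (nt < 1) stop("series too short for embedding length m");
  const double* p = x.begin();
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int c = 0;
    for (int j = 0; j < nt; ++j)
      if (cheb_match(p, i, j, m, r)) ++c;
    acc += std::log((double)c / nt);
  }
  return acc / nt;
}

// Sample-entropy match counts: over unordered pairs i < j of the n - m
// templates, B counts Chebyshev matches of length m and A matches of
// length m + 1 (self-matches excluded by construction).
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // templates comparable at both lengths m and m + 1
  if (nt < 2) stop("series too short for embedding length m");
  const double* p = x.begin();
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (cheb_match(p, i, j, m, r)) {
        B += 1.0;
        double d = p[i + m] - p[j + m];
        if (d <= r && d >= -r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
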