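#include <Rcpp.h>
using namespace Rcpp;

// Pair counts for sample entropy: templates of length m (N - m of them,
// so every template has an (m+1)-sample extension), Chebyshev distance,
// self-matches excluded. Returns (B, A): m-length and (m+1)-length match
// counts over unordered pairs.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dk = std::fabs(x[i + m] - x[j + m]);
        if (dk > d) d = dk;
        if (d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Mean fuzzy memberships (phi_m, phi_m1) for fuzzy entropy: templates are
// baseline-centred (template mean removed), membership exp(-(d/r)^p) with
// Chebyshev d, averaged over unordered pairs; N - m templates for both
// lengths.
// [[Rcpp::export]]
NumericVector fuzzyen_phis(NumericVector x, int m, double r, double p) {
  int n = x.size();
  int nt = n - m;
  // centred templates of length m and m+1
  std::vector<double> cm(nt * m), cm1(nt * (m + 1));
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    double mu = s / m;
    for (int k = 0; k < m; ++k) cm[i * m + k] = x[i + k] - mu;
    s += x[i + m];
    double mu1 = s / (m + 1);
    for (int k = 0; k <= m; ++k) cm1[i * (m + 1) + k] = x[i + k] - mu1;
  }
  double phim = 0.0, phim1 = 0.0;
  long npairs = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(cm[i * m + k] - cm[j * m + k]);
        if (dk > d) d = dk;
      }
      phim += std::exp(-std::pow(d / r, p));
      d = 0.0;
      for (int k = 0; k <= m; ++k) {
        double dk = std::fabs(cm1[i * (m + 1) + k] - cm1[j * (m + 1) + k]);
        if (dk > d) d = dk;
      }
      phim1 += std::exp(-std::pow(d / r, p));
      ++npairs;
    }
  }
  return NumericVector::create(phim / npairs, phim1 / npairs);
}
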