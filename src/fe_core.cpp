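#include <Rcpp.h>
using namespace Rcpp;

// Pattern-match degrees phi at embedding dimensions m and m+1 for a series x,
// with exponential fuzzy membership exp(-d^n / r) over Chebyshev distances.
// Returns c(phi_m, phi_m1). Normalisation: mean over ordered pairs i != j,
// i.e. sum / (W * (W - 1)) with W the number of embedded vectors at that
// dimension. Caller guarantees length(x) >= m + 2 and r > 0.
// [[Rcpp::export(name = ".fe_phi_pair")]]
NumericVector fe_phi_pair(NumericVector x, int m, double r, double n) {
  const int N = x.size();
  const int Wm = N - m + 1; // vectors at dimension m
  const int W1 = N - m;     // vectors at dimension m + 1
  const bool sq = (n == 2.0);
  double sm = 0.0, s1 = 0.0;
  for (int i = 0; i < Wm - 1; ++i) {
    for (int j = i + 1; j < Wm; ++j) {
      double dm = 0.0;
      for (int t = 0; t < m; ++t) {
        double d = std::fabs(x[i + t] - x[j + t]);
        if (d > dm) dm = d;
      }
      sm += std::exp(-(sq ? dm * dm : std::pow(dm, n)) / r);
      if (j < W1) {
        // both windows extend to dimension m + 1
        double d1 = std::fabs(x[i + m] - x[j + m]);
        if (dm > d1) d1 = dm;
        s1 += std::exp(-(sq ? d1 * d1 : std::pow(d1, n)) / r);
      }
    }
  }
  const double phim = (2.0 * sm) / (static_cast<double>(Wm) * (Wm - 1));
  const double phi1 = (2.0 * s1) / (static_cast<double>(W1) * (W1 - 1));
  return NumericVector::create(phim, phi1);
}
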