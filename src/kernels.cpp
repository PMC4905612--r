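#include <Rcpp.h>
using namespace Rcpp;

// Concentration score S = N * R^2 of the feature positions at each candidate
// period.  Uses theta_i = 2*pi*pos_i/P directly: taking positions modulo P
// first changes nothing (angles are equal mod 2*pi) and costs an extra pass.
// [[Rcpp::export]]
NumericVector scan_scores_cpp(NumericVector positions, NumericVector periods) {
  R_xlen_t n = positions.size(), k = periods.size();
  std::vector<double> pos(positions.begin(), positions.end());
  NumericVector S(k);
  for (R_xlen_t j = 0; j < k; ++j) {
    double w = 2.0 * M_PI / periods[j];
    double c = 0.0, s = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double a = pos[i] * w;
      c += std::cos(a);
      s += std::sin(a);
    }
    S[j] = (c * c + s * s) / n;
  }
  return S;
}

// Null replicates of S at a single period: n positions drawn uniformly on
// [1, G].  Uses R's RNG so set.seed() on the R side makes draws reproducible.
// [[Rcpp::export]]
NumericVector null_scores_cpp(int n, double period, double genome_length,
                              int n_mc) {
  NumericVector out(n_mc);
  double w = 2.0 * M_PI / period;
  for (int r = 0; r < n_mc; ++r) {
    double c = 0.0, s = 0.0;
    for (int i = 0; i < n; ++i) {
      double pos = 1.0 + unif_rand() * (genome_length - 1.0);
      c += std::cos(pos * w);
      s += std::sin(pos * w);
    }
    out[r] = (c * c + s * s) / n;
  }
  return out;
}

// Scan-wide null: for each of n_null uniform feature sets of size n, the
// maximum score over the whole period grid.  The empirical distribution of
// these maxima calibrates the corrected p-value of a scan exactly.
// [[Rcpp::export]]
NumericVector null_max_scores_cpp(int n, NumericVector periods,
                                  double genome_length, int n_null) {
  R_xlen_t k = periods.size();
  std::vector<double> w(k);
  for (R_xlen_t j = 0; j < k; ++j) w[j] = 2.0 * M_PI / periods[j];
  std::vector<double> pos(n);
  NumericVector out(n_null);
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < n; ++i)
      pos[i] = 1.0 + unif_rand() * (genome_length - 1.0);
    double best = 0.0;
    for (R_xlen_t j = 0; j < k; ++j) {
      double c = 0.0, s = 0.0;
      for (int i = 0; i < n; ++i) {
        double a = pos[i] * w[j];
        c += std::cos(a);
        s += std::sin(a);
      }
      double S = (c * c + s * s) / n;
      if (S > best) best = S;
    }
    out[r] = best;
  }
  return out;
}
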