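#include <Rcpp.h>
using namespace Rcpp;

// Two-state (non-ROH = 0, ROH = 1) Viterbi path along one chromosome.
// le: 2 x n matrix of log emission probabilities (row 0 = non-ROH).
// d_cm: n-1 genetic gaps in cM between consecutive covered sites.
// theta: ROH entry rate per cM; exit_rate: 1/mean ROH length per cM.
// Transition matrix over a gap d is the exact 2-state CTMC exponential.
// [[Rcpp::export]]
IntegerVector viterbi_two_state(NumericMatrix le, NumericVector d_cm,
                                double theta, double exit_rate) {
  int n = le.ncol();
  IntegerVector path(n);
  if (n == 0) return path;
  double pi1 = theta / (theta + exit_rate);  // stationary P(ROH)
  std::vector<double> v0(n), v1(n);
  std::vector<signed char> bp0(n), bp1(n);
  v0[0] = std::log(1.0 - pi1) + le(0, 0);
  v1[0] = std::log(pi1) + le(1, 0);
  double s = theta + exit_rate;
  for (int t = 1; t < n; ++t) {
    double e = std::exp(-s * d_cm[t - 1]);
    double p01 = (theta / s) * (1.0 - e);
    double p10 = (exit_rate / s) * (1.0 - e);
    double l00 = std::log(1.0 - p01), l01 = std::log(p01);
    double l10 = std::log(p10), l11 = std::log(1.0 - p10);
    double a0 = v0[t - 1] + l00, b0 = v1[t - 1] + l10;
    if (a0 >= b0) { v0[t] = a0 + le(0, t); bp0[t] = 0; }
    else          { v0[t] = b0 + le(0, t); bp0[t] = 1; }
    double a1 = v0[t - 1] + l01, b1 = v1[t - 1] + l11;
    if (a1 >= b1) { v1[t] = a1 + le(1, t); bp1[t] = 0; }
    else          { v1[t] = b1 + le(1, t); bp1[t] = 1; }
  }
  int state = v1[n - 1] > v0[n - 1] ? 1 : 0;
  path[n - 1] = state;
  for (int t = n - 1; t > 0; --t) {
    state = state == 0 ? bp0[t] : bp1[t];
    path[t - 1] = state;
  }
  return path;
}
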