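#include <Rcpp.h>
using namespace Rcpp;

// Window scores over probe index ranges [first, last] (1-based, inclusive).
// Windows are contiguous runs of position-sorted probes, so the permutation
// loop only pays O(total window span) per shuffle.

// Trimmed mean: drop exactly one maximal and one minimal value, average the
// rest. Windows with fewer than 3 probes get NA (callers exclude them).
// [[Rcpp::export]]
NumericVector cpp_trimmed_scores(NumericVector y, IntegerVector first,
                                 IntegerVector last) {
  const int W = first.size();
  NumericVector out(W);
  for (int w = 0; w < W; ++w) {
    const int a = first[w] - 1, b = last[w] - 1;
    const int n = b - a + 1;
    if (n < 3) { out[w] = NA_REAL; continue; }
    double s = 0.0, mx = R_NegInf, mn = R_PosInf;
    for (int i = a; i <= b; ++i) {
      const double v = y[i];
      s += v;
      if (v > mx) mx = v;
      if (v < mn) mn = v;
    }
    out[w] = (s - mx - mn) / (n - 2);
  }
  return out;
}

// Differential score: window direction is the sign of the summed per-probe
// differences (zero-sum ties break to +1); probes whose difference opposes
// the direction are discarded; the score is the signed mean of the rest.
// [[Rcpp::export]]
List cpp_diff_scores(NumericVector d, IntegerVector first,
                     IntegerVector last) {
  const int W = first.size();
  NumericVector score(W);
  IntegerVector dir(W);
  for (int w = 0; w < W; ++w) {
    const int a = first[w] - 1, b = last[w] - 1;
    const int n = b - a + 1;
    if (n < 1) { score[w] = NA_REAL; dir[w] = NA_INTEGER; continue; }
    double s = 0.0;
    for (int i = a; i <= b; ++i) s += d[i];
    const int g = (s >= 0.0) ? 1 : -1;
    double rs = 0.0;
    int rn = 0;
    for (int i = a; i <= b; ++i) {
      const double v = d[i];
      if (g > 0 ? (v >= 0.0) : (v <= 0.0)) { rs += v; ++rn; }
    }
    score[w] = rs / rn;  // rn >= 1: the majority sign always has members
    dir[w] = g;
  }
  return List::create(_["score"] = score, _["direction"] = dir);
}
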