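#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear gap cost, flat beyond the last breakpoint.
static double pl_cost(double x, const NumericVector& brk,
                      const NumericVector& cst) {
  int n = brk.size();
  if (x <= brk[0]) return cst[0];
  for (int i = 1; i < n; ++i) {
    if (x <= brk[i]) {
      double f = (x - brk[i - 1]) / (brk[i] - brk[i - 1]);
      return cst[i - 1] + f * (cst[i] - cst[i - 1]);
    }
  }
  return cst[n - 1];
}

// Best-predecessor chaining DP over blocks of one (query, strand)
// partition, sorted by ref_start.  Coordinates are 0-based half-open;
// query coordinates are forward-strand.  On '-' partitions the chain
// traverses the query in decreasing forward coordinates.
// [[Rcpp::export(name = ".chain_dp")]]
List chain_dp(NumericVector rs, NumericVector re, NumericVector qs,
              NumericVector qe, NumericVector score, bool minus,
              NumericVector brk1, NumericVector cst1,
              NumericVector brk2, NumericVector cst2) {
  int n = rs.size();
  NumericVector dp(n);
  IntegerVector pred(n, -1);
  NumericVector predgap(n);
  for (int i = 0; i < n; ++i) {
    double best = 0.0, bestgap = 0.0;
    int bestj = -1;
    for (int j = 0; j < i; ++j) {
      if (re[j] > rs[i]) continue;
      double dq;
      if (!minus) {
        if (qe[j] > qs[i]) continue;
        dq = qs[i] - qe[j];
      } else {
        if (qe[i] > qs[j]) continue;
        dq = qs[j] - qe[i];
      }
      double dr = rs[i] - re[j];
      double cost;
      if (dr > 0 && dq > 0) cost = pl_cost(dr + dq, brk2, cst2);
      else cost = pl_cost(dr + dq, brk1, cst1);
      double cand = dp[j] - cost;
      double gap = dr + dq;
      if (cand > best || (cand == best && bestj >= 0 && gap < bestgap)) {
        best = cand; bestj = j; bestgap = gap;
      }
    }
    if (best <= 0.0) { best = 0.0; bestj = -1; bestgap = 0.0; }
    dp[i] = score[i] + best;
    pred[i] = bestj;
    predgap[i] = bestgap;
  }
  return List::create(_["dp"] = dp, _["pred"] = pred);
}
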