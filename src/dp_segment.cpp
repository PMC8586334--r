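#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact penalized least-squares change-point DP over a trace of n samples.
// Fragment cost is the RSS of an independent OLS line, computed O(1) from
// cumulative sums of the (centered) time and value series. F[j] holds the
// optimal cost of samples [0, j) charging one penalty per fragment; the
// caller subtracts one penalty so breakpoints, not fragments, are charged.
//
// Candidates are pruned PELT-style (Killick et al. 2012): RSS is subadditive
// across a split, so a candidate whose partial cost already exceeds the
// incumbent by more than the penalty margin can never become optimal again.
// Pruning keeps the exact optimum; the margin (one penalty, and only
// candidates older than 2*min_size) is deliberately conservative because of
// the minimum-segment-length constraint.
//
// [[Rcpp::export(name = ".dp_segment_cpp")]]
List dp_segment_cpp(NumericVector cx, NumericVector cy, NumericVector cxx,
                    NumericVector cyy, NumericVector cxy, int n,
                    double penalty, int min_size) {
  NumericVector Fv(n + 1, R_PosInf);
  IntegerVector prevv(n + 1, 0);
  double *F = REAL(Fv);
  int *prev = INTEGER(prevv);
  const double *px = REAL(cx), *py = REAL(cy), *pxx = REAL(cxx),
               *pyy = REAL(cyy), *pxy = REAL(cxy);
  std::vector<double> inv(n + 1, 0.0);
  for (int m = 1; m <= n; ++m) inv[m] = 1.0 / m;
  F[0] = 0.0;

  std::vector<int> cand;
  cand.reserve(256);
  cand.push_back(0);
  std::vector<double> rss_of(n + 1, 0.0);

  for (int j = min_size; j <= n; ++j) {
    int enter = j - min_size;  // candidate becoming eligible at this j
    if (enter > 0 && enter >= min_size && F[enter] < R_PosInf) {
      cand.push_back(enter);
    }
    double best = R_PosInf;
    int best_i = 0;
    for (size_t q = 0; q < cand.size(); ++q) {
      int i = cand[q];
      double im = inv[j - i];
      double sx = px[j] - px[i];
      double sy = py[j] - py[i];
      double vx = (pxx[j] - pxx[i]) - sx * sx * im;
      double vy = (pyy[j] - pyy[i]) - sy * sy * im;
      double cv = (pxy[j] - pxy[i]) - sx * sy * im;
      double rss = vy - cv * cv / vx;
      if (rss < 0) rss = 0;
      rss_of[i] = rss;
      double tot = F[i] + rss + penalty;
      if (tot < best) {
        best = tot;
        best_i = i;
      }
    }
    F[j] = best;
    prev[j] = best_i;
    // prune settled candidates that can never be optimal again
    size_t keep = 0;
    for (size_t q = 0; q < cand.size(); ++q) {
      int i = cand[q];
      if (i > j - 2 * min_size ||
          F[i] + rss_of[i] <= F[j] + penalty) {
        cand[keep++] = i;
      }
    }
    cand.resize(keep);
  }
  return List::create(_["F"] = Fv, _["prev"] = prevv);
}
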