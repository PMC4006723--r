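#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Poisson segmentation of binned counts.
//
// Segment cost is twice the negative maximised Poisson log-likelihood up to
// a data-only constant: C(i..j) = 2 * (x - x * log(x / n)) with x the total
// count and n the number of bins (C = 0 when x = 0, the lambda-hat = 0
// limit).  Costs are additive over segments, so both solvers below share the
// same objective and differ only in how the number of segments is chosen.

static inline double seg_cost(const std::vector<double>& cx, int i, int j) {
  double x = cx[j] - cx[i - 1];
  if (x <= 0.0) return 0.0;
  double n = j - i + 1;
  return 2.0 * (x - x * std::log(x / n));
}

// Exact dynamic program over a fixed number of segments.
// Returns, for each K = 1..kmax, the optimal cost and the segment end
// indices (1-based, inclusive).  minlen constrains every segment length.
// [[Rcpp::export(name = ".dp_segment_cpp")]]
List dp_segment_cpp(NumericVector counts, int kmax, int minlen) {
  const int n = counts.size();
  const double INF = std::numeric_limits<double>::infinity();
  if (n < 1 || kmax < 1 || minlen < 1) stop("invalid DP arguments");
  std::vector<double> cx(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cx[i + 1] = cx[i] + counts[i];

  // F(k, t): optimal cost of covering bins 1..t with (k+1) segments.
  NumericMatrix F(kmax, n + 1);
  IntegerMatrix back(kmax, n + 1);
  for (int t = 0; t <= n; ++t) {
    F(0, t) = (t >= minlen) ? seg_cost(cx, 1, t) : INF;
    back(0, t) = 0;
  }
  for (int k = 1; k < kmax; ++k) {
    for (int t = 0; t <= n; ++t) {
      double best = INF;
      int arg = -1;
      for (int s = (k)*minlen; s <= t - minlen; ++s) {
        if (!std::isfinite(F(k - 1, s))) continue;
        double v = F(k - 1, s) + seg_cost(cx, s + 1, t);
        if (v < best) { best = v; arg = s; }
      }
      F(k, t) = best;
      back(k, t) = arg;
    }
  }
  List paths(kmax);
  NumericVector costs(kmax);
  for (int k = 0; k < kmax; ++k) {
    costs[k] = F(k, n);
    if (!std::isfinite(F(k, n))) { paths[k] = IntegerVector(0); continue; }
    std::vector<int> ends;
    int t = n;
    for (int kk = k; kk >= 1; --kk) {
      ends.push_back(t);
      t = back(kk, t);
    }
    ends.push_back(t);
    std::reverse(ends.begin(), ends.end());
    paths[k] = wrap(ends);
  }
  return List::create(_["cost"] = costs, _["ends"] = paths);
}

// PELT solver for the linearly penalised objective
//   min over segmentations  sum_segments C(seg) + penalty * (#segments).
// Equivalent to choosing K by penalised selection over the fixed-K DP when
// the penalty is linear in K; pruning keeps it near-linear in n.
// [[Rcpp::export(name = ".pelt_segment_cpp")]]
IntegerVector pelt_segment_cpp(NumericVector counts, double penalty,
                               int minlen) {
  const int n = counts.size();
  const double INF = std::numeric_limits<double>::infinity();
  if (n < 1 || minlen < 1) stop("invalid PELT arguments");
  std::vector<double> cx(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cx[i + 1] = cx[i] + counts[i];

  std::vector<double> F(n + 1, INF);
  std::vector<int> last(n + 1, 0);
  F[0] = -penalty;
  std::vector<int> cand;
  cand.push_back(0);
  for (int t = 1; t <= n; ++t) {
    double best = INF;
    int arg = 0;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int s = cand[ci];
      if (t - s < minlen) continue;
      double v = F[s] + seg_cost(cx, s + 1, t) + penalty;
      if (v < best) { best = v; arg = s; }
    }
    F[t] = best;
    last[t] = arg;
    if (std::isfinite(best)) {
      // prune candidates that can never be optimal again
      std::vector<int> keep;
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        int s = cand[ci];
        if (t - s < minlen || F[s] + seg_cost(cx, s + 1, t) <= F[t]) {
          keep.push_back(s);
        }
      }
      cand.swap(keep);
      cand.push_back(t);
    }
  }
  if (!std::isfinite(F[n])) stop("no feasible segmentation (minlen too large)");
  std::vector<int> ends;
  int t = n;
  while (t > 0) {
    ends.push_back(t);
    t = last[t];
  }
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
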