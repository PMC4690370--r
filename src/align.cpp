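#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment (Gotoh three-state affine DP) with a fixed,
// documented tie-break order.  The deterministic traceback is part of the
// package contract (identical inputs give identical variant calls and
// identity values), which is why this lives here rather than behind a
// generic aligner:
//   * at equal score, match/mismatch beats a gap in `b` (deletion relative
//     to `a`), which beats a gap in `a` (insertion);
//   * at equal score, extending an open gap beats opening a new one, so
//     equal-cost edit scripts resolve to contiguous indel runs.
// A gap of length g scores gap_open + g * gap_ext (gap_open = 0 gives the
// plain linear-gap Needleman-Wunsch; an infinitesimal gap_open is used by the
// variant caller purely to disambiguate equal-cost unit edit scripts).
//
// a, b: 1-based integer-encoded sequences (codes index into S).
// Returns aligned index vectors (0 = gap) and the optimal score.
// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_ext, double gap_open = 0.0) {
  const int n = a.size(), m = b.size();
  if ((double)(n + 1) * (double)(m + 1) > 9e7)
    stop("alignment problem too large (%d x %d)", n, m);
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: PM in {0:M,1:X,2:Y} = predecessor state of M's diagonal step;
  // PX in {0:open from M, 1:extend X, 2:open from Y}; PY likewise.
  IntegerMatrix PM(n + 1, m + 1), PX(n + 1, m + 1), PY(n + 1, m + 1);
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = gap_open + i * gap_ext; PX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = gap_open + j * gap_ext; PY(0, j) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      // M: diagonal step from the best previous state (prefer M, then X, then Y)
      double best = M(i - 1, j - 1); int p = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); p = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); p = 2; }
      M(i, j) = best + S(ai, b[j - 1] - 1); PM(i, j) = p;
      // X: gap in b (consume a); prefer extension at equal score
      double x = X(i - 1, j) + gap_ext; int px = 1;
      const double xo = M(i - 1, j) + gap_open + gap_ext;
      if (xo > x) { x = xo; px = 0; }
      const double xy = Y(i - 1, j) + gap_open + gap_ext;
      if (xy > x) { x = xy; px = 2; }
      X(i, j) = x; PX(i, j) = px;
      // Y: gap in a (consume b); prefer extension at equal score
      double y = Y(i, j - 1) + gap_ext; int py = 1;
      const double yo = M(i, j - 1) + gap_open + gap_ext;
      if (yo > y) { y = yo; py = 0; }
      const double yx = X(i, j - 1) + gap_open + gap_ext;
      if (yx > y) { y = yx; py = 2; }
      Y(i, j) = y; PY(i, j) = py;
    }
  }
  // final state: prefer M, then X, then Y at equal score
  int state = 0; double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }
  std::vector<int> ai_out, bi_out;
  ai_out.reserve(n + m); bi_out.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const int p = PM(i, j);
      ai_out.push_back(i); bi_out.push_back(j);
      --i; --j; state = p;
    } else if (state == 1) {
      const int p = PX(i, j);
      ai_out.push_back(i); bi_out.push_back(0);
      --i; state = (p == 1) ? 1 : (p == 0 ? 0 : 2);
    } else {
      const int p = PY(i, j);
      ai_out.push_back(0); bi_out.push_back(j);
      --j; state = (p == 1) ? 2 : (p == 0 ? 0 : 1);
    }
  }
  std::reverse(ai_out.begin(), ai_out.end());
  std::reverse(bi_out.begin(), bi_out.end());
  return List::create(_["a_idx"] = wrap(ai_out),
                      _["b_idx"] = wrap(bi_out),
                      _["score"] = score);
}

// Longest strictly increasing subsequence (patience sorting, O(n log n)).
// Returns 1-based indices of a maximum-cardinality strictly increasing
// subsequence of x; among equals the construction keeps the smallest
// attainable values, matching the "smaller alt_pos wins ties" rule.
// [[Rcpp::export]]
IntegerVector lis_cpp(IntegerVector x) {
  const int n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tail_idx;  // tail_idx[k]: index of smallest tail of a LIS of length k+1
  std::vector<int> parent(n, -1);
  for (int i = 0; i < n; ++i) {
    int lo = 0, hi = (int)tail_idx.size();
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (x[tail_idx[mid]] < x[i]) lo = mid + 1; else hi = mid;
    }
    if (lo == (int)tail_idx.size()) tail_idx.push_back(i); else tail_idx[lo] = i;
    parent[i] = lo > 0 ? tail_idx[lo - 1] : -1;
  }
  const int len = (int)tail_idx.size();
  IntegerVector out(len);
  int cur = tail_idx[len - 1];
  for (int k = len - 1; k >= 0; --k) { out[k] = cur + 1; cur = parent[cur]; }
  return out;
}
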