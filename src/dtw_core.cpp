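#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping under an L1 local cost.
// pattern: 1 = symmetric1 (all steps weight local cost once),
//          2 = symmetric2 (diagonal step weighs local cost twice).
// window:  Sakoe-Chiba band half-width on |i - j|; < 0 means unconstrained.
// Cells outside the band stay +Inf; the caller guarantees
// window >= |n - m| so the corner (n, m) is always reachable.

static inline double l1(double x, double y) { return std::fabs(x - y); }

// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector a, NumericVector b, int pattern, int window,
              bool backtrack) {
  const int n = a.size(), m = b.size();
  const double diagw = (pattern == 2) ? 2.0 : 1.0;
  NumericMatrix D(n, m);
  IntegerMatrix step(backtrack ? n : 1, backtrack ? m : 1);
  std::fill(D.begin(), D.end(), R_PosInf);

  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (window >= 0) {
      jlo = std::max(0, i - window);
      jhi = std::min(m - 1, i + window);
    }
    for (int j = jlo; j <= jhi; ++j) {
      const double c = l1(a[i], b[j]);
      if (i == 0 && j == 0) {
        D(0, 0) = c;
        if (backtrack) step(0, 0) = 0;
        continue;
      }
      double best = R_PosInf;
      int how = 0;
      if (i > 0 && j > 0 && R_finite(D(i - 1, j - 1))) {
        best = D(i - 1, j - 1) + diagw * c;
        how = 1;  // diagonal
      }
      if (i > 0 && R_finite(D(i - 1, j))) {
        const double v = D(i - 1, j) + c;
        if (v < best) { best = v; how = 2; }  // from (i-1, j)
      }
      if (j > 0 && R_finite(D(i, j - 1))) {
        const double v = D(i, j - 1) + c;
        if (v < best) { best = v; how = 3; }  // from (i, j-1)
      }
      D(i, j) = best;
      if (backtrack) step(i, j) = how;
    }
  }

  double dist = D(n - 1, m - 1);
  if (!backtrack)
    return List::create(_["distance"] = dist);

  // walk the recorded predecessors back from the corner
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (true) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    const int how = step(i, j);
    if (how == 0) break;
    if (how == 1) { --i; --j; }
    else if (how == 2) { --i; }
    else { --j; }
  }
  const int len = pi.size();
  IntegerMatrix path(len, 2);
  for (int r = 0; r < len; ++r) {
    path(r, 0) = pi[len - 1 - r];
    path(r, 1) = pj[len - 1 - r];
  }
  return List::create(_["distance"] = dist, _["path"] = path);
}

// All-pairs DTW distances for equal-length series stored as matrix rows.
// [[Rcpp::export(name = ".dtw_pairwise")]]
NumericMatrix dtw_pairwise(NumericMatrix X, int pattern, int window) {
  const int n = X.nrow();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      NumericVector a = X(i, _), b = X(j, _);
      List r = dtw_core(a, b, pattern, window, false);
      const double d = as<double>(r["distance"]);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
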