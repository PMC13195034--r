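#include <Rcpp.h>
using namespace Rcpp;

// Monotone residue-correspondence DP over a per-pair similarity matrix.
// Global alignment with free end gaps and a flat internal gap penalty;
// ties resolve toward the diagonal (match), then toward consuming the
// first chain, making the traceback deterministic.
// Returns a 2-column integer matrix of 1-based (i, j) matched pairs.
// [[Rcpp::export(name = ".dp_align_cpp")]]
IntegerMatrix dp_align_cpp(NumericMatrix score, double gap) {
  int n = score.nrow(), m = score.ncol();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix from(n + 1, m + 1); // 1 = diag, 2 = up (gap in j), 3 = left
  for (int i = 0; i <= n; ++i) { S(i, 0) = 0.0; from(i, 0) = 2; }
  for (int j = 0; j <= m; ++j) { S(0, j) = 0.0; from(0, j) = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) + score(i - 1, j - 1);
      double up = S(i - 1, j) - (j == m ? 0.0 : gap);
      double left = S(i, j - 1) - (i == n ? 0.0 : gap);
      double best = diag; int dir = 1;
      if (up > best + 1e-12) { best = up; dir = 2; }
      if (left > best + 1e-12) { best = left; dir = 3; }
      S(i, j) = best; from(i, j) = dir;
    }
  }
  // traceback from (n, m)
  std::vector<int> pi, pj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    int dir = from(i, j);
    if (dir == 1) { pi.push_back(i); pj.push_back(j); --i; --j; }
    else if (dir == 2) --i;
    else --j;
  }
  int k = pi.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = pi[k - 1 - r];
    out(r, 1) = pj[k - 1 - r];
  }
  return out;
}
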