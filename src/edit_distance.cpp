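#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>
using namespace Rcpp;

// Capped semi-global (infix) Levenshtein distance between a short probe and
// a longer text: minimum unit-cost edit distance between the probe and any
// substring of the text.  Row 0 of the DP matrix is free (a match may start
// anywhere); the answer is the minimum over the last row (it may end
// anywhere).  Ukkonen cut-off: per column only the prefix of cells with
// value <= cap is maintained; inactive cells act as cap + 1, which can only
// over-report values that are already beyond the cap, so every value <= cap
// is exact.  'N' never matches any base, itself included.
//
// Returns c(distance, end) where end is the 0-based half-open end offset of
// the best match in the text (smallest end wins ties), or c(-1, -1) when the
// true minimum exceeds cap.
// [[Rcpp::export(name = ".infix_edit_cpp")]]
IntegerVector infix_edit_cpp(const std::string& probe, const std::string& gene,
                             int cap) {
  const int m = (int) probe.size();
  const int n = (int) gene.size();
  if (m < 1) stop("probe must have length >= 1");
  if (cap < 0) stop("cap must be >= 0");

  std::vector<int> col(m + 1);
  for (int i = 0; i <= m; ++i) col[i] = i;
  const int big = cap + 1;
  int lac = std::min(m, cap);   // last active cell (value <= cap)
  int best = m;                 // empty infix: delete the whole probe
  int bestEnd = 0;

  for (int j = 1; j <= n && best > 0; ++j) {
    const char gc = gene[j - 1];
    const int upTo = std::min(m, lac + 1);
    int prevDiag = col[0];      // D[0][j-1] == 0
    col[0] = 0;
    for (int i = 1; i <= upTo; ++i) {
      const char pc = probe[i - 1];
      const int cost = (pc == gc && pc != 'N') ? 0 : 1;
      const int old = (i <= lac) ? col[i] : big;
      int v = std::min(std::min(old + 1, col[i - 1] + 1), prevDiag + cost);
      if (v > big) v = big;
      col[i] = v;
      prevDiag = old;
    }
    int newLac = upTo;
    while (newLac > 0 && col[newLac] > cap) --newLac;
    lac = newLac;
    if (upTo == m && col[m] < best) {
      best = col[m];
      bestEnd = j;
    }
  }

  if (best > cap) return IntegerVector::create(-1, -1);
  return IntegerVector::create(best, bestEnd);
}
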