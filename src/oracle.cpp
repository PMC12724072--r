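#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Independent reference implementation: plain O(|pattern| * |text|) scalar
// edit-distance scan with free start (Sellers). Shares no code with the
// index-based search machinery; used as the correctness oracle.
//
// Returns, for every end position e = 0..|text|, the minimal edit distance
// between the pattern and any substring of the text ending at e.
// [[Rcpp::export]]
IntegerVector cpp_oracle_scan(IntegerVector text, IntegerVector pattern) {
  int n = text.size(), m = pattern.size();
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int match = (text[j - 1] == pattern[i - 1] &&
                   text[j - 1] >= 1 && text[j - 1] <= 4) ? 0 : 1;
      int best = prev[j - 1] + match;
      if (prev[j] + 1 < best) best = prev[j] + 1;
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return IntegerVector(prev.begin(), prev.end());
}

// Exhaustive error-vector coverage check for a search scheme: enumerates all
// vectors (a_1..a_p) with sum <= k and tests each against every search's
// cumulative bounds in its processing order. Returns the first uncovered
// vector, or an empty vector when the scheme covers everything.
// pis/Ls/Us: one row per search (p columns each); pi 0-based.
// [[Rcpp::export]]
IntegerVector cpp_coverage_witness(IntegerMatrix pis, IntegerMatrix Ls,
                                   IntegerMatrix Us, int p, int k) {
  int ns = pis.nrow();
  std::vector<int> a(p, 0);
  // odometer over all vectors with sum <= k
  while (true) {
    int sum = 0;
    for (int i = 0; i < p; ++i) sum += a[i];
    bool admitted = false;
    for (int s = 0; s < ns && !admitted; ++s) {
      bool ok = true;
      int cum = 0;
      for (int i = 0; i < p && ok; ++i) {
        cum += a[pis(s, i)];
        if (cum < Ls(s, i) || cum > Us(s, i)) ok = false;
      }
      if (ok) admitted = true;
    }
    if (!admitted) return IntegerVector(a.begin(), a.end());
    // next vector with sum <= k
    int i = p - 1;
    while (i >= 0) {
      int others = 0;
      for (int j = 0; j < p; ++j) if (j != i) others += a[j];
      if (a[i] + others < k) { a[i] += 1; break; }
      a[i] = 0; --i;
    }
    if (i < 0) break;
  }
  return IntegerVector(0);
}
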