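#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exported banded-row computations: bit-parallel (Myers-style delta vectors)
// and a plain scalar reference. Both return the full (|text|+1) x (|pattern|+1)
// matrix with NA outside the band |row - col| <= k and values capped at k+1
// inside it. Cells whose true value exceeds k are reported as k+1.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_banded_rows_bitpar(IntegerVector pattern, IntegerVector text, int k) {
  if (k < 0 || k > SS_KMAX) stop("band half-width k must be in 0..%d", SS_KMAX);
  int plen = pattern.size(), tlen = text.size();
  int w = 2 * k + 1;
  uint64_t maskW = (w >= 64) ? ~0ULL : ((1ULL << w) - 1);
  // per-character pattern masks (bit j = pattern position j)
  int words = (plen + 63) / 64;
  std::vector<std::vector<uint64_t>> pm(SS_SIGMA, std::vector<uint64_t>(std::max(words, 1), 0));
  for (int j = 0; j < plen; ++j) {
    int c = pattern[j];
    if (c >= 1 && c <= 4) pm[c][j >> 6] |= (1ULL << (j & 63));
  }
  IntegerMatrix out(tlen + 1, plen + 1);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  Band S = ss_band_init(k);
  for (int m = 0; m <= tlen; ++m) {
    if (m > 0) {
      int c = text[m - 1];
      uint64_t Eq = (c >= 1 && c <= 4) ? ss_eq_window(pm[c], plen, S.m - k, w, maskW) : 0;
      S = ss_band_step(S, Eq, k);
    }
    for (int col = std::max(0, m - k); col <= std::min(plen, m + k); ++col) {
      int64_t v = ss_band_cell(S, col, k);
      out(m, col) = (int)std::min<int64_t>(v, k + 1);
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_banded_rows_scalar(IntegerVector pattern, IntegerVector text, int k) {
  if (k < 0) stop("k must be non-negative");
  int plen = pattern.size(), tlen = text.size();
  // plain full dynamic programme, then band mask + cap
  std::vector<std::vector<int>> D(tlen + 1, std::vector<int>(plen + 1, 0));
  for (int j = 0; j <= plen; ++j) D[0][j] = j;
  for (int i = 1; i <= tlen; ++i) {
    D[i][0] = i;
    for (int j = 1; j <= plen; ++j) {
      int sub = (text[i - 1] == pattern[j - 1] &&
                 text[i - 1] >= 1 && text[i - 1] <= 4) ? 0 : 1;
      D[i][j] = std::min(std::min(D[i - 1][j] + 1, D[i][j - 1] + 1),
                         D[i - 1][j - 1] + sub);
    }
  }
  IntegerMatrix out(tlen + 1, plen + 1);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  for (int i = 0; i <= tlen; ++i)
    for (int j = std::max(0, i - k); j <= std::min(plen, i + k); ++j)
      out(i, j) = std::min(D[i][j], k + 1);
  return out;
}

// ---------------------------------------------------------------------------
// Multi-word Myers scan: minimal edit distance of the pattern against any
// substring of `txt` ending at each position (free start). Used for in-text
// verification. Returns d for ends 0..|txt|.
// ---------------------------------------------------------------------------
std::vector<int> ss_myers_scan(const std::vector<uint8_t>& txt,
                               const std::vector<uint8_t>& pat) {
  int m = (int)pat.size(), n = (int)txt.size();
  std::vector<int> out(n + 1);
  if (m == 0) { std::fill(out.begin(), out.end(), 0); return out; }
  int W = (m + 63) / 64;
  std::vector<std::vector<uint64_t>> pmv(SS_SIGMA, std::vector<uint64_t>(W, 0));
  for (int j = 0; j < m; ++j) {
    int c = pat[j];
    if (c >= 1 && c <= 4) pmv[c][j >> 6] |= (1ULL << (j & 63));
  }
  uint64_t lastmask = (m % 64 == 0) ? ~0ULL : ((1ULL << (m % 64)) - 1);
  uint64_t lastbit = 1ULL << ((m - 1) % 64);
  std::vector<uint64_t> VP(W, ~0ULL), VN(W, 0);
  VP[W - 1] &= lastmask;
  int score = m;
  out[0] = score;
  for (int i = 0; i < n; ++i) {
    int c = txt[i];
    const std::vector<uint64_t>& pmc =
      (c >= 1 && c <= 4) ? pmv[c] : pmv[0];
    uint64_t carryAdd = 0, carryHP = 0, carryHN = 0;
    for (int b = 0; b < W; ++b) {
      uint64_t Eq = pmc[b];
      uint64_t X = Eq | VN[b];
      uint64_t XV = X & VP[b];
      // (XV + VP + carry) with explicit carry between words
      uint64_t sum1 = XV + VP[b];
      uint64_t c1 = (sum1 < XV) ? 1 : 0;
      uint64_t sum = sum1 + carryAdd;
      uint64_t c2 = (sum < sum1) ? 1 : 0;
      carryAdd = c1 | c2;
      uint64_t D0 = (sum ^ VP[b]) | X;
      uint64_t HP = VN[b] | ~(D0 | VP[b]);
      uint64_t HN = D0 & VP[b];
      if (b == W - 1) {
        if (HP & lastbit) ++score;
        else if (HN & lastbit) --score;
      }
      uint64_t HPs = (HP << 1) | carryHP;
      uint64_t HNs = (HN << 1) | carryHN;
      carryHP = HP >> 63;
      carryHN = HN >> 63;
      VP[b] = HNs | ~(HPs | D0);
      VN[b] = HPs & D0;
      if (b == W - 1) { VP[b] &= lastmask; VN[b] &= lastmask; }
    }
    out[i + 1] = score;
  }
  return out;
}

// Leftmost start of a minimal-distance alignment of `pat` against a substring
// of `txt` ending at `end` (local coordinates); searches at most |pat|+k back.
// Returns (start, d).
std::pair<int, int> ss_best_start(const std::vector<uint8_t>& txt, int end,
                                  const std::vector<uint8_t>& pat, int k) {
  int m = (int)pat.size();
  int span = std::min(end, m + k);
  // reverse DP: D[i][l] = distance of last i pattern chars vs last l text chars
  std::vector<int> prev(span + 1), cur(span + 1);
  for (int l = 0; l <= span; ++l) prev[l] = l;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int l = 1; l <= span; ++l) {
      uint8_t tc = txt[end - l];
      uint8_t pc = pat[m - i];
      int sub = (tc == pc && tc >= 1 && tc <= 4) ? 0 : 1;
      cur[l] = std::min(std::min(prev[l] + 1, cur[l - 1] + 1), prev[l - 1] + sub);
    }
    std::swap(prev, cur);
  }
  int bestd = INT32_MAX, bestl = 0;
  for (int l = 0; l <= span; ++l) {
    if (prev[l] < bestd || (prev[l] == bestd && l > bestl)) {
      bestd = prev[l]; bestl = l;   // longest l = leftmost start
    }
  }
  return std::make_pair(end - bestl, bestd);
}

// [[Rcpp::export]]
IntegerVector cpp_scan_ends(IntegerVector window, IntegerVector pattern) {
  std::vector<uint8_t> txt(window.begin(), window.end());
  std::vector<uint8_t> pat(pattern.begin(), pattern.end());
  std::vector<int> d = ss_myers_scan(txt, pat);
  return IntegerVector(d.begin(), d.end());
}

// All canonical hits of `pattern` inside a text window: for every end with
// minimal distance <= k, the leftmost minimal-distance start. Local 0-based
// half-open coordinates within the window.
// [[Rcpp::export]]
DataFrame cpp_canonical_hits(IntegerVector window, IntegerVector pattern, int k) {
  std::vector<uint8_t> txt(window.begin(), window.end());
  std::vector<uint8_t> pat(pattern.begin(), pattern.end());
  std::vector<int> dm = ss_myers_scan(txt, pat);
  std::vector<int> S, E, D;
  for (int e = 0; e <= (int)txt.size(); ++e) {
    if (dm[e] <= k) {
      std::pair<int, int> sd = ss_best_start(txt, e, pat, k);
      S.push_back(sd.first); E.push_back(e); D.push_back(sd.second);
    }
  }
  return DataFrame::create(_["start"] = S, _["end"] = E, _["d"] = D);
}

// Global alignment of pattern against a reference slice with traceback.
// Tie-break preference: match > substitution > deletion (ref-consuming, 'D')
// > insertion (read-consuming, 'I'). 'M' covers match and mismatch.
// [[Rcpp::export]]
List cpp_align_global(IntegerVector ref_slice, IntegerVector pattern) {
  int n = ref_slice.size(), m = pattern.size();
  std::vector<std::vector<int>> D(n + 1, std::vector<int>(m + 1));
  for (int j = 0; j <= m; ++j) D[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    D[i][0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = (ref_slice[i - 1] == pattern[j - 1] &&
                 ref_slice[i - 1] >= 1 && ref_slice[i - 1] <= 4) ? 0 : 1;
      D[i][j] = std::min(std::min(D[i - 1][j] + 1, D[i][j - 1] + 1),
                         D[i - 1][j - 1] + sub);
    }
  }
  // traceback
  std::string ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int sub = (i > 0 && j > 0 &&
               ref_slice[i - 1] == pattern[j - 1] &&
               ref_slice[i - 1] >= 1 && ref_slice[i - 1] <= 4) ? 0 : 1;
    if (i > 0 && j > 0 && sub == 0 && D[i][j] == D[i - 1][j - 1]) {
      ops.push_back('M'); --i; --j;
    } else if (i > 0 && j > 0 && D[i][j] == D[i - 1][j - 1] + 1) {
      ops.push_back('M'); --i; --j;           // substitution
    } else if (i > 0 && D[i][j] == D[i - 1][j] + 1) {
      ops.push_back('D'); --i;                // extra reference base
    } else {
      ops.push_back('I'); --j;                // extra read base
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cigar;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cigar += std::to_string(q - p);
    cigar.push_back(ops[p]);
    p = q;
  }
  if (cigar.empty()) cigar = "*";
  return List::create(_["d"] = D[n][m], _["cigar"] = cigar);
}
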