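#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Depth-first execution of a single search (pi, L, U) of a search scheme over
// the bidirectional FM-index.
//
// The pattern is anchored at the boundary ("cut") where the first part is
// matched. Text grown to the right of the anchor is aligned against the
// pattern region right of the cut with a banded row (struct Band); text grown
// to the left is aligned against the reversed pattern region left of the cut
// with its own banded row. Any alignment of an occurrence can be split at the
// cut column, so the sum of the two banded rows' boundary cells bounds the
// occurrence's distance, and the branch whose text split matches the
// alignment's crossing row computes it exactly. Completion of a part is
// attempted at every row where the part's final column lies inside the band,
// which is what makes the search lossless under direction switches.
//
// When the range width drops below `thr`, the branch switches to in-text
// verification: candidates are located and the full pattern is verified
// bit-parallel against a window that provably contains every occurrence
// compatible with the partial match.
// ---------------------------------------------------------------------------

namespace {

struct Ctx {
  const FMIndex* fm;
  int k, w, p, plen, cut, thr;
  uint64_t maskW;
  std::vector<uint8_t> pat;                       // full pattern codes
  std::vector<std::vector<uint64_t>> pmR, pmL;    // per-char masks, each region
  int lenR, lenL;
  std::vector<int> sideOf, colEnd, otherEnd;      // per step (0 = L, 1 = R)
  std::vector<int> Lb, Ub;
  std::vector<double> oS, oE;                     // output occurrences
  std::vector<int> oD, oSrc;
  long nodes;
};

const int64_t INF = INT64_MAX / 4;

void report_range(Ctx& C, const BiRange& rg, int mL, int mR, int d, int src) {
  std::vector<int64_t> pos = ss_locate(*C.fm, rg.b, rg.e);
  for (size_t i = 0; i < pos.size(); ++i) {
    C.oS.push_back((double)pos[i]);
    C.oE.push_back((double)(pos[i] + mL + mR));
    C.oD.push_back(d);
    C.oSrc.push_back(src);
  }
}

void verify_in_text(Ctx& C, const BiRange& rg, const Band& L, const Band& R) {
  std::vector<int64_t> pos = ss_locate(*C.fm, rg.b, rg.e);
  int n = C.fm->n;
  for (size_t i = 0; i < pos.size(); ++i) {
    int64_t lo = pos[i] + L.m - C.cut - 2 * C.k;
    int64_t hi = pos[i] + L.m + (C.plen - C.cut) + 2 * C.k;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;          // exclude sentinel
    if (hi <= lo) continue;
    std::vector<uint8_t> win(C.fm->text.begin() + lo, C.fm->text.begin() + hi);
    std::vector<int> dm = ss_myers_scan(win, C.pat);
    for (int e = 0; e <= (int)win.size(); ++e) {
      if (dm[e] <= C.k) {
        std::pair<int, int> sd = ss_best_start(win, e, C.pat, C.k);
        C.oS.push_back((double)(lo + sd.first));
        C.oE.push_back((double)(lo + e));
        C.oD.push_back(sd.second);
        C.oSrc.push_back(1);
      }
    }
  }
}

void advance(Ctx& C, int step, const BiRange& rg, const Band& L, const Band& R) {
  if ((++C.nodes & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  if (step == C.p) {
    int64_t dL = ss_band_cell(L, C.lenL, C.k);
    int64_t dR = ss_band_cell(R, C.lenR, C.k);
    if (dL >= INF || dR >= INF) return;
    int64_t d = dL + dR;
    if (d <= C.k && d <= C.Ub[C.p - 1] && d >= C.Lb[C.p - 1])
      report_range(C, rg, L.m, R.m, (int)d, 0);
    return;
  }
  bool right = C.sideOf[step] == 1;
  const Band& cur = right ? R : L;
  const Band& oth = right ? L : R;
  int ce = C.colEnd[step];
  int64_t othEnd = ss_band_cell(oth, C.otherEnd[step], C.k);
  if (othEnd >= INF) return;

  // in-text verification: few candidates left, finish against the text
  if (rg.width() > 0 && rg.width() < C.thr) {
    verify_in_text(C, rg, L, R);
    return;
  }

  // complete the current part at the current row, if its final column is
  // inside the band and the cumulative bound admits it
  if (ce <= cur.m + C.k && ce >= cur.m - C.k) {
    int64_t v = ss_band_cell(cur, ce, C.k);
    if (v + othEnd <= C.Ub[step] && v + othEnd <= C.k)
      advance(C, step + 1, rg, L, R);
  }

  // extend by one character while further rows could still complete the part
  if (cur.m + 1 <= ce + C.k) {
    const std::vector<std::vector<uint64_t>>& pm = right ? C.pmR : C.pmL;
    int len = right ? C.lenR : C.lenL;
    for (int c = 1; c <= 5; ++c) {
      BiRange rg2 = right ? ss_extend_right(*C.fm, rg, c)
                          : ss_extend_left(*C.fm, rg, c);
      if (rg2.empty()) continue;
      uint64_t Eq = (c <= 4)
        ? ss_eq_window(pm[c], len, cur.m - C.k, C.w, C.maskW) : 0;
      Band nb = ss_band_step(cur, Eq, C.k);
      if (ss_band_min(nb, ce, C.k) + othEnd > C.Ub[step]) continue;
      if (ss_band_min(nb, len, C.k) + othEnd > C.k) continue;
      if (right) advance(C, step, rg2, L, nb);
      else       advance(C, step, rg2, nb, R);
    }
  }
}

}  // namespace

// cuts: p+1 0-based cut positions (cuts[0] = 0, cuts[p] = |pattern|)
// pi: 0-based processing order; L, U: cumulative bounds per processed part
// [[Rcpp::export]]
DataFrame cpp_execute_search(SEXP xp, IntegerVector pattern, IntegerVector cuts,
                             IntegerVector pi, IntegerVector Lb, IntegerVector Ub,
                             int k, int thr) {
  XPtr<FMIndex> fmp(xp);
  if (k < 0 || k > SS_KMAX) stop("k must be in 0..%d", SS_KMAX);
  Ctx C;
  C.fm = fmp.get();
  C.k = k; C.w = 2 * k + 1;
  C.maskW = (C.w >= 64) ? ~0ULL : ((1ULL << C.w) - 1);
  C.p = pi.size();
  C.plen = pattern.size();
  C.thr = thr;
  C.nodes = 0;
  C.pat.assign(pattern.begin(), pattern.end());
  C.Lb.assign(Lb.begin(), Lb.end());
  C.Ub.assign(Ub.begin(), Ub.end());

  int s0 = pi[0];
  bool firstRight = (C.p == 1) || (pi[1] > s0);
  C.cut = firstRight ? cuts[s0] : cuts[s0 + 1];
  C.lenL = C.cut;
  C.lenR = C.plen - C.cut;

  int wordsR = std::max(1, (C.lenR + 63) / 64);
  int wordsL = std::max(1, (C.lenL + 63) / 64);
  C.pmR.assign(SS_SIGMA, std::vector<uint64_t>(wordsR, 0));
  C.pmL.assign(SS_SIGMA, std::vector<uint64_t>(wordsL, 0));
  for (int j = 0; j < C.lenR; ++j) {
    int c = C.pat[C.cut + j];
    if (c >= 1 && c <= 4) C.pmR[c][j >> 6] |= (1ULL << (j & 63));
  }
  for (int j = 0; j < C.lenL; ++j) {       // reversed left region
    int c = C.pat[C.cut - 1 - j];
    if (c >= 1 && c <= 4) C.pmL[c][j >> 6] |= (1ULL << (j & 63));
  }

  C.sideOf.resize(C.p); C.colEnd.resize(C.p); C.otherEnd.resize(C.p);
  int curL = 0, curR = 0;
  for (int i = 0; i < C.p; ++i) {
    int q = pi[i];
    bool right = (q > s0) || (q == s0 && firstRight);
    C.sideOf[i] = right ? 1 : 0;
    C.colEnd[i] = right ? (cuts[q + 1] - C.cut) : (C.cut - cuts[q]);
    C.otherEnd[i] = right ? curL : curR;
    if (right) curR = C.colEnd[i]; else curL = C.colEnd[i];
  }

  BiRange rg = ss_full_range(*C.fm);
  Band L0 = ss_band_init(k), R0 = ss_band_init(k);
  advance(C, 0, rg, L0, R0);

  return DataFrame::create(_["start"] = NumericVector(C.oS.begin(), C.oS.end()),
                           _["end"] = NumericVector(C.oE.begin(), C.oE.end()),
                           _["d"] = IntegerVector(C.oD.begin(), C.oD.end()),
                           _["source"] = IntegerVector(C.oSrc.begin(), C.oSrc.end()));
}
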