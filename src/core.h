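// Shared internals for the bidirectional FM-index and the banded
// bit-parallel alignment machinery.
//
// Character codes used throughout: 0 = sentinel '$', 1..4 = A,C,G,T,
// 5 = reserved fifth character (any non-ACGT base; matches nothing).
#ifndef SSALIGNER_CORE_H
#define SSALIGNER_CORE_H

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>
#include <algorithm>

static const int SS_SIGMA = 6;     // alphabet incl. sentinel and fifth char
static const int SS_KMAX  = 13;    // hard ceiling on errors per read

struct FMIndex {
  int n;                            // text length including sentinel
  int sample;                       // SA sampling factor
  std::vector<uint8_t> text;        // sanitized text, sentinel (0) last
  std::vector<uint8_t> bwtF, bwtR;  // BWT of text and of reversed text
  std::array<int64_t, SS_SIGMA + 1> C;  // C[c] = # characters < c
  // Full per-position prefix counts (block size 1): occ[(i*SIGMA)+c] =
  // # occurrences of c in bwt[0, i). O(1) rank at desk scale.
  std::vector<int32_t> occF, occR;
  // Row-indexed sampled SA over the forward text: markF[row] = SA[row]
  // when SA[row] %% sample == 0, else -1; locate LF-walks <= sample steps.
  std::vector<int32_t> markF;

  inline int64_t rankF(int c, int64_t i) const { return occF[i * SS_SIGMA + c]; }
  inline int64_t rankR(int c, int64_t i) const { return occR[i * SS_SIGMA + c]; }
};

std::vector<int32_t> ss_build_sa(const std::vector<uint8_t>& s);

struct BiRange {            // half-open synchronized interval pair
  int64_t b, e, rb, re;
  inline int64_t width() const { return e - b; }
  inline bool empty() const { return e <= b; }
};

BiRange ss_full_range(const FMIndex& fm);
BiRange ss_extend_left(const FMIndex& fm, const BiRange& r, int c);
BiRange ss_extend_right(const FMIndex& fm, const BiRange& r, int c);
std::vector<int64_t> ss_locate(const FMIndex& fm, int64_t b, int64_t e);

// ---- banded bit-parallel row state ----------------------------------------
//
// One row of the banded edit-distance matrix between a grown text string
// (rows, one per consumed character) and a fixed pattern region (columns).
// Row m covers columns [m-k, m+k]; bit b of HP/HN is the horizontal delta
// D(m, m-k+b) - D(m, m-k+b-1) (+1 / -1); `score` is D(m, m+k), the
// rightmost in-band cell. Cells with true value > k may be overestimated
// (band edge saturation); all cells with true value <= k are exact.
struct Band {
  uint64_t HP, HN;
  int64_t score;
  int m;
};

inline Band ss_band_init(int k) {
  int w = 2 * k + 1;
  uint64_t maskW = (w >= 64) ? ~0ULL : ((1ULL << w) - 1);
  Band s;
  // row 0: value at column j is |j| (virtual never-match columns j<0)
  s.HP = 0; s.HN = 0;
  for (int b = 0; b < w; ++b) {
    if (b <= k) s.HN |= (1ULL << b); else s.HP |= (1ULL << b);
  }
  s.HP &= maskW; s.HN &= maskW;
  s.score = k;
  s.m = 0;
  return s;
}

// One text character consumed; Eq bit b = (pattern char at column
// (m+1-k+b) equals the character), i.e. pattern index m-k+b (0-based).
inline Band ss_band_step(const Band& S, uint64_t Eq, int k) {
  int w = 2 * k + 1;
  uint64_t maskW = (w >= 64) ? ~0ULL : ((1ULL << w) - 1);
  uint64_t topbit = 1ULL << (w - 1);
  // shift the previous row's deltas down by one (diagonal band moves right);
  // the vacated top delta is +1 (band-edge saturation, sound for values <= k)
  uint64_t VP = ((S.HP >> 1) | topbit) & maskW;
  uint64_t VN = (S.HN >> 1) & maskW;
  uint64_t X  = (Eq | VN) & maskW;
  uint64_t D0 = (((((X & VP) + VP) & maskW) ^ VP) | X) & maskW;
  uint64_t HNo = VP & D0;
  uint64_t HPo = (VN | ~(VP | D0)) & maskW;
  Band out;
  out.score = S.score + 1 + ((HPo & topbit) ? 1 : 0) - ((HNo & topbit) ? 1 : 0);
  uint64_t Y = ((HPo << 1) | 1ULL) & maskW;
  out.HP = ((HNo << 1) | ~(Y | D0)) & maskW;
  out.HN = (Y & D0) & maskW;
  out.m = S.m + 1;
  return out;
}

// value of cell at pattern-region column `col` in the current row;
// INT64_MAX/4 if outside the band.
inline int64_t ss_band_cell(const Band& S, int col, int k) {
  int w = 2 * k + 1;
  int b = col - (S.m - k);
  if (b < 0 || b >= w) return INT64_MAX / 4;
  int64_t v = S.score;
  for (int bb = w - 1; bb > b; --bb) {
    if (S.HP & (1ULL << bb)) v -= 1;
    else if (S.HN & (1ULL << bb)) v += 1;
  }
  return v;
}

// min over in-band cells at real region columns in [0, colMax]
inline int64_t ss_band_min(const Band& S, int colMax, int k) {
  int w = 2 * k + 1;
  int64_t v = S.score, best = INT64_MAX / 4;
  for (int b = w - 1; b >= 0; --b) {
    int col = S.m - k + b;
    if (col >= 0 && col <= colMax && v < best) best = v;
    if (S.HP & (1ULL << b)) v -= 1;
    else if (S.HN & (1ULL << b)) v += 1;
  }
  return best;
}

// pattern-match bitmask extraction: bits b = 0..w-1 map to pattern index
// start+b of the region's per-character mask words; out-of-range bits are 0.
inline uint64_t ss_eq_window(const std::vector<uint64_t>& pm, int len,
                             int start, int w, uint64_t maskW) {
  if (start >= len || start <= -w) return 0;
  uint64_t r = 0;
  for (int b = 0; b < w; ++b) {
    int j = start + b;
    if (j < 0 || j >= len) continue;
    if (pm[j >> 6] & (1ULL << (j & 63))) r |= (1ULL << b);
  }
  return r & maskW;
}

std::vector<int> ss_myers_scan(const std::vector<uint8_t>& txt,
                               const std::vector<uint8_t>& pat);
std::pair<int, int> ss_best_start(const std::vector<uint8_t>& txt, int end,
                                  const std::vector<uint8_t>& pat, int k);

#endif
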