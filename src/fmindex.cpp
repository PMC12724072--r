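#include "core.h"
using namespace Rcpp;

// Suffix array by prefix doubling (O(n log^2 n)); adequate at desk scale and
// independent of any external suffix-sorting library.
std::vector<int32_t> ss_build_sa(const std::vector<uint8_t>& s) {
  int n = (int)s.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = s[i]; }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = (a + len < n) ? rnk[a + len] : -1;
      int rb = (b + len < n) ? rnk[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1 || len >= n) break;
  }
  return std::vector<int32_t>(sa.begin(), sa.end());
}

static void build_occ(const std::vector<uint8_t>& bwt,
                      std::vector<int32_t>& occ) {
  int n = (int)bwt.size();
  occ.assign((size_t)(n + 1) * SS_SIGMA, 0);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < SS_SIGMA; ++c)
      occ[(size_t)(i + 1) * SS_SIGMA + c] = occ[(size_t)i * SS_SIGMA + c];
    occ[(size_t)(i + 1) * SS_SIGMA + bwt[i]] += 1;
  }
}

// codes: sanitized reference without sentinel, values in 1..5
// [[Rcpp::export]]
SEXP cpp_index_build(IntegerVector codes, int sample) {
  if (codes.size() == 0) stop("empty reference after sanitization");
  if (sample < 1) stop("SA sampling factor must be >= 1");
  FMIndex* fm = new FMIndex();
  int n = codes.size() + 1;
  fm->n = n;
  fm->sample = sample;
  fm->text.resize(n);
  for (int i = 0; i < n - 1; ++i) {
    int c = codes[i];
    if (c < 1 || c > 5) { delete fm; stop("invalid character code %d", c); }
    fm->text[i] = (uint8_t)c;
  }
  fm->text[n - 1] = 0;

  std::vector<uint8_t> rev(n);
  for (int i = 0; i < n - 1; ++i) rev[i] = fm->text[n - 2 - i];
  rev[n - 1] = 0;

  std::vector<int32_t> saF = ss_build_sa(fm->text);
  std::vector<int32_t> saR = ss_build_sa(rev);

  fm->bwtF.resize(n); fm->bwtR.resize(n);
  for (int i = 0; i < n; ++i) {
    fm->bwtF[i] = fm->text[(saF[i] + n - 1) % n];
    fm->bwtR[i] = rev[(saR[i] + n - 1) % n];
  }
  std::array<int64_t, SS_SIGMA> cnt; cnt.fill(0);
  for (int i = 0; i < n; ++i) cnt[fm->text[i]] += 1;
  fm->C[0] = 0;
  for (int c = 1; c <= SS_SIGMA; ++c) fm->C[c] = fm->C[c - 1] + cnt[c - 1];

  build_occ(fm->bwtF, fm->occF);
  build_occ(fm->bwtR, fm->occR);

  fm->markF.assign(n, -1);
  for (int i = 0; i < n; ++i)
    if (saF[i] % sample == 0) fm->markF[i] = saF[i];

  XPtr<FMIndex> ptr(fm, true);
  return ptr;
}

static FMIndex* get_fm(SEXP xp) {
  XPtr<FMIndex> p(xp);
  if (!p) stop("invalid index pointer");
  return p.get();
}

// [[Rcpp::export]]
int cpp_index_n(SEXP xp) { return get_fm(xp)->n; }

// [[Rcpp::export]]
int cpp_index_sample(SEXP xp) { return get_fm(xp)->sample; }

// [[Rcpp::export]]
IntegerVector cpp_index_bwt(SEXP xp, bool reverse) {
  FMIndex* fm = get_fm(xp);
  const std::vector<uint8_t>& b = reverse ? fm->bwtR : fm->bwtF;
  return IntegerVector(b.begin(), b.end());
}

// [[Rcpp::export]]
IntegerVector cpp_index_text(SEXP xp, int from, int to) {
  FMIndex* fm = get_fm(xp);
  from = std::max(from, 0); to = std::min(to, fm->n);
  if (to < from) to = from;
  return IntegerVector(fm->text.begin() + from, fm->text.begin() + to);
}

BiRange ss_full_range(const FMIndex& fm) {
  return BiRange{0, fm.n, 0, fm.n};
}

BiRange ss_extend_left(const FMIndex& fm, const BiRange& r, int c) {
  BiRange out;
  out.b = fm.C[c] + fm.rankF(c, r.b);
  out.e = fm.C[c] + fm.rankF(c, r.e);
  int64_t smaller = 0;
  for (int a = 0; a < c; ++a) smaller += fm.rankF(a, r.e) - fm.rankF(a, r.b);
  out.rb = r.rb + smaller;
  out.re = out.rb + (out.e - out.b);
  return out;
}

BiRange ss_extend_right(const FMIndex& fm, const BiRange& r, int c) {
  BiRange out;
  out.rb = fm.C[c] + fm.rankR(c, r.rb);
  out.re = fm.C[c] + fm.rankR(c, r.re);
  int64_t smaller = 0;
  for (int a = 0; a < c; ++a) smaller += fm.rankR(a, r.re) - fm.rankR(a, r.rb);
  out.b = r.b + smaller;
  out.e = out.b + (out.re - out.rb);
  return out;
}

std::vector<int64_t> ss_locate(const FMIndex& fm, int64_t b, int64_t e) {
  std::vector<int64_t> out;
  for (int64_t i = b; i < e; ++i) {
    int64_t j = i, steps = 0;
    while (fm.markF[j] < 0) {
      int c = fm.bwtF[j];
      j = fm.C[c] + fm.rankF(c, j);   // LF step: SA[j'] = SA[j] - 1
      ++steps;
    }
    out.push_back(fm.markF[j] + steps);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_full_range(SEXP xp) {
  FMIndex* fm = get_fm(xp);
  BiRange r = ss_full_range(*fm);
  return NumericVector::create((double)r.b, (double)r.e, (double)r.rb, (double)r.re);
}

// [[Rcpp::export]]
NumericVector cpp_extend(SEXP xp, NumericVector range, int c, bool left) {
  FMIndex* fm = get_fm(xp);
  if (c < 1 || c > 5) stop("extension character code must be in 1..5");
  BiRange r{(int64_t)range[0], (int64_t)range[1], (int64_t)range[2], (int64_t)range[3]};
  BiRange out = left ? ss_extend_left(*fm, r, c) : ss_extend_right(*fm, r, c);
  return NumericVector::create((double)out.b, (double)out.e, (double)out.rb, (double)out.re);
}

// [[Rcpp::export]]
NumericVector cpp_locate(SEXP xp, double b, double e) {
  FMIndex* fm = get_fm(xp);
  std::vector<int64_t> pos = ss_locate(*fm, (int64_t)b, (int64_t)e);
  NumericVector out(pos.size());
  for (size_t i = 0; i < pos.size(); ++i) out[i] = (double)pos[i];
  return out;
}

// [[Rcpp::export]]
double cpp_count_exact(SEXP xp, IntegerVector pattern) {
  FMIndex* fm = get_fm(xp);
  BiRange r = ss_full_range(*fm);
  for (int i = pattern.size() - 1; i >= 0; --i) {
    int c = pattern[i];
    // codes outside A,C,G,T (incl. the reserved fifth character, which
    // matches nothing) admit no exact occurrence
    if (c < 1 || c > 4) return 0;
    r = ss_extend_left(*fm, r, c);
    if (r.empty()) return 0;
  }
  return (double)r.width();
}
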