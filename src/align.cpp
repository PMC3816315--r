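#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>
#include "ovl_internal.h"

// Unit scoring: match +1, mismatch -1, gap -1. 'N' never matches anything.
static inline bool base_match(char x, char y) {
  return x == y && x != 'N';
}

static const int NEG = INT_MIN / 4;

// Banded overlap (free-end-gap) alignment of a against b, restricted to
// diagonals j - i within [d - band, d + band] where d is the seed diagonal
// (b offset minus a offset). First row/column cells inside the band are free
// (score 0); the best score over the last row and last column is taken and
// traced back to a boundary. Ties broken diagonal > up > left, and among
// terminal cells the first strictly-better one in a fixed scan order wins
// (last column by ascending row, then last row by ascending column).
ovl_aln banded_overlap_core(const char* a, int la, const char* b, int lb,
                            int d, int band) {
  ovl_aln out; out.ok = false;
  if (la == 0 || lb == 0 || band < 1) return out;
  const int W = 2 * band + 1;
  const int lo_diag = d - band;  // j - i >= lo_diag
  // reusable buffers (one allocation amortized across calls)
  static std::vector<int> S;
  static std::vector<signed char> D;
  const size_t need = (size_t)(la + 1) * W;
  if (S.size() < need) { S.resize(need); D.resize(need); }
  std::fill(S.begin(), S.begin() + need, NEG);
  std::fill(D.begin(), D.begin() + need, (signed char) 0);

  // boundary cells (free end gaps); band column of (i, j) is j - i - lo_diag
  for (int j = std::max(0, lo_diag); j <= std::min(lb, d + band); ++j)
    S[j - lo_diag] = 0;
  for (int i = 0; i <= la; ++i) {
    const int c = -i - lo_diag;
    if (c >= 0 && c < W) S[(size_t) i * W + c] = 0;
  }
  for (int i = 1; i <= la; ++i) {
    int* row = S.data() + (size_t) i * W;
    const int* prev = row - W;
    signed char* drow = D.data() + (size_t) i * W;
    const char ai = a[i - 1];
    const int jlo = std::max(1, i + lo_diag);
    const int jhi = std::min(lb, i + d + band);
    for (int j = jlo; j <= jhi; ++j) {
      const int c = j - i - lo_diag;
      int best = prev[c] + (base_match(ai, b[j - 1]) ? 1 : -1);
      signed char dir = 1;
      if (c + 1 < W) {
        const int up = prev[c + 1] - 1;
        if (up > best) { best = up; dir = 2; }
      }
      if (c >= 1) {
        const int left = row[c - 1] - 1;
        if (left > best) { best = left; dir = 3; }
      }
      if (best <= NEG / 2) continue;
      row[c] = best; drow[c] = dir;
    }
  }

  int best = NEG, bi = -1, bj = -1;
  for (int i = 0; i <= la; ++i) {
    const int c = lb - i - lo_diag;
    if (c < 0 || c >= W) continue;
    const int s = S[(size_t) i * W + c];
    if (s > best) { best = s; bi = i; bj = lb; }
  }
  for (int j = std::max(0, la + lo_diag); j <= std::min(lb, la + d + band); ++j) {
    const int s = S[(size_t) la * W + (j - la - lo_diag)];
    if (s > best) { best = s; bi = la; bj = j; }
  }
  if (bi < 0 || best <= NEG / 2) return out;

  int i = bi, j = bj, columns = 0, matches = 0;
  while (i > 0 && j > 0) {
    const signed char dir = D[(size_t) i * W + (j - i - lo_diag)];
    if (dir == 0) break;  // free boundary reached inside band
    ++columns;
    if (dir == 1) {
      if (base_match(a[i - 1], b[j - 1])) ++matches;
      --i; --j;
    } else if (dir == 2) {
      --i;
    } else {
      --j;
    }
  }
  if (columns == 0) return out;
  out.score = best; out.columns = columns; out.matches = matches;
  out.a0 = i; out.a1 = bi; out.b0 = j; out.b1 = bj; out.ok = true;
  return out;
}

static inline long long qgram_code(const char* s, int q) {
  long long h = 0;
  for (int t = 0; t < q; ++t) {
    int v;
    switch (s[t]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default:  v = 4; break;
    }
    h = h * 5 + v;
  }
  return h;
}

// q-gram lemma pre-filter: two strings within e edit operations share at
// least w + 1 - q*(e+1) q-grams (multiset intersection), w = min(|a|, |b|).
// A threshold <= 0 always passes, so the filter has no false negatives.
bool qgram_pass_core(const char* a, int la, const char* b, int lb,
                     int q, int max_errors) {
  const int w = std::min(la, lb);
  const int t = w + 1 - q * (max_errors + 1);
  if (t <= 0) return true;
  if (la < q || lb < q) return false;
  static std::vector<long long> ha, hb;
  ha.clear(); hb.clear();
  for (int i = 0; i + q <= la; ++i) ha.push_back(qgram_code(a + i, q));
  for (int i = 0; i + q <= lb; ++i) hb.push_back(qgram_code(b + i, q));
  std::sort(ha.begin(), ha.end());
  std::sort(hb.begin(), hb.end());
  int cnt = 0; size_t i = 0, j = 0;
  while (i < ha.size() && j < hb.size()) {
    if (ha[i] < hb[j]) ++i;
    else if (hb[j] < ha[i]) ++j;
    else { ++cnt; ++i; ++j; }
  }
  return cnt >= t;
}

// [[Rcpp::export(name = ".banded_overlap_cpp")]]
Rcpp::NumericVector banded_overlap_cpp(const std::string& a,
                                       const std::string& b,
                                       int d, int band) {
  ovl_aln r = banded_overlap_core(a.data(), (int) a.size(),
                                  b.data(), (int) b.size(), d, band);
  if (!r.ok) return Rcpp::NumericVector(0);
  return Rcpp::NumericVector::create(
      (double) r.score, (double) r.columns, (double) r.matches,
      (double) r.a0, (double) r.a1, (double) r.b0, (double) r.b1);
}

// [[Rcpp::export(name = ".qgram_pass_cpp")]]
bool qgram_pass_cpp(const std::string& a, const std::string& b,
                    int q, int max_errors) {
  return qgram_pass_core(a.data(), (int) a.size(), b.data(), (int) b.size(),
                         q, max_errors);
}
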