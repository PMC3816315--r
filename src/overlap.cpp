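#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>
#include "ovl_internal.h"

// compare the k-length prefix of the suffix at pos against text[p0, p0+k)
static inline int cmp_k(const std::string& text, int pos, int p0, int k) {
  const int n = (int) text.size();
  for (int t = 0; t < k; ++t) {
    if (pos + t >= n) return -1;
    const unsigned char x = (unsigned char) text[pos + t];
    const unsigned char y = (unsigned char) text[p0 + t];
    if (x != y) return x < y ? -1 : 1;
  }
  return 0;
}

// suffix-array interval of suffixes starting with text[p0, p0+k)
static inline void sa_interval(const std::string& text,
                               const Rcpp::IntegerVector& sa,
                               int p0, int k, int& lo_out, int& hi_out) {
  int lo = 0, hi = sa.size();
  while (lo < hi) {
    const int mid = lo + (hi - lo) / 2;
    if (cmp_k(text, sa[mid], p0, k) < 0) lo = mid + 1; else hi = mid;
  }
  lo_out = lo;
  hi = sa.size();
  while (lo < hi) {
    const int mid = lo + (hi - lo) / 2;
    if (cmp_k(text, sa[mid], p0, k) <= 0) lo = mid + 1; else hi = mid;
  }
  hi_out = lo;
}

static inline bool clean_kmer(const std::string& text, int p0, int k) {
  for (int t = 0; t < k; ++t) {
    const char c = text[p0 + t];
    if (c == 'N' || c == '$') return false;
  }
  return true;
}

static std::vector<int> read_of_position(const std::string& text,
                                         const Rcpp::IntegerVector& read_start,
                                         const Rcpp::IntegerVector& read_len) {
  std::vector<int> r(text.size(), -1);
  for (int i = 0; i < read_start.size(); ++i)
    for (int p = read_start[i]; p < read_start[i] + read_len[i]; ++p) r[p] = i;
  return r;
}

// All exact k-mer seed hits of one query read against the other reads in the
// index (self-read hits excluded). Columns: ref_id, query_offset,
// ref_text_position, diagonal (= ref offset - query offset); all 0-based.
// [[Rcpp::export(name = ".find_seed_hits_cpp")]]
Rcpp::DataFrame find_seed_hits_cpp(const std::string& text,
                                   const Rcpp::IntegerVector& sa,
                                   const Rcpp::IntegerVector& read_start,
                                   const Rcpp::IntegerVector& read_len,
                                   int query_id, int k, int stride) {
  std::vector<int> pos2read = read_of_position(text, read_start, read_len);
  std::vector<int> rv, ov, pv, dv;
  const int qs = read_start[query_id], ql = read_len[query_id];
  for (int o = 0; o + k <= ql; o += stride) {
    const int p0 = qs + o;
    if (!clean_kmer(text, p0, k)) continue;
    int lo, hi;
    sa_interval(text, sa, p0, k, lo, hi);
    for (int t = lo; t < hi; ++t) {
      const int p = sa[t];
      const int rid = pos2read[p];
      if (rid < 0 || rid == query_id) continue;
      const int roff = p - read_start[rid];
      rv.push_back(rid); ov.push_back(o); pv.push_back(p);
      dv.push_back(roff - o);
    }
  }
  return Rcpp::DataFrame::create(
      Rcpp::Named("ref_id") = rv, Rcpp::Named("query_offset") = ov,
      Rcpp::Named("ref_text_position") = pv, Rcpp::Named("diagonal") = dv);
}

// true iff suffixes at p1 and p2 agree on their first k characters
static inline bool equal_k(const std::string& text, int p1, int p2, int k) {
  const int n = (int) text.size();
  if (p1 + k > n || p2 + k > n) return false;
  const char* a = text.data() + p1;
  const char* b = text.data() + p2;
  for (int t = 0; t < k; ++t) if (a[t] != b[t]) return false;
  return true;
}

// Full overlapper: for each query read, enumerate component k-mer seeds,
// locate exact matches via the suffix array (k-prefix groups of the suffix
// array are precomputed once, so a seed's match interval is an O(1) lookup
// through the inverse suffix array), deduplicate candidate (reference,
// diagonal) pairs (reference id > query id so each unordered pair is
// evaluated once), cluster nearby diagonals within the band, q-gram filter
// the implied overlap windows, then banded overlap alignment; keep overlaps
// with alignment length >= min_len and identity >= min_id, best alignment
// per pair (longest, then highest identity, then smallest diagonal).
// [[Rcpp::export(name = ".overlap_all_cpp")]]
Rcpp::List overlap_all_cpp(const std::string& text,
                           const Rcpp::IntegerVector& sa,
                           const Rcpp::IntegerVector& read_start,
                           const Rcpp::IntegerVector& read_len,
                           int k, int q, int band, int min_len, double min_id,
                           int stride) {
  const int n = read_start.size();
  const int nT = (int) text.size();
  std::vector<int> pos2read = read_of_position(text, read_start, read_len);

  // rank = inverse suffix array; gstart/gend delimit runs of suffixes that
  // share their first k characters
  std::vector<int> rank(nT), gstart(nT), gend(nT);
  for (int i = 0; i < nT; ++i) rank[sa[i]] = i;
  gstart[0] = 0;
  for (int i = 1; i < nT; ++i)
    gstart[i] = equal_k(text, sa[i - 1], sa[i], k) ? gstart[i - 1] : i;
  gend[nT - 1] = nT - 1;
  for (int i = nT - 2; i >= 0; --i)
    gend[i] = (gstart[i + 1] == gstart[i]) ? gend[i + 1] : i;

  std::vector<int> out_q, out_r, out_len;
  std::vector<double> out_id;
  long long n_candidates = 0;
  std::vector<std::pair<int, int>> cand;  // (ref, diagonal)

  for (int qid = 0; qid < n; ++qid) {
    const int qs = read_start[qid], ql = read_len[qid];
    if (ql < k) continue;
    cand.clear();
    for (int o = 0; o + k <= ql; o += stride) {
      const int p0 = qs + o;
      if (!clean_kmer(text, p0, k)) continue;
      const int r0 = rank[p0];
      for (int t = gstart[r0]; t <= gend[r0]; ++t) {
        const int rid = pos2read[sa[t]];
        if (rid <= qid) continue;  // each unordered pair evaluated once
        cand.push_back({rid, (sa[t] - read_start[rid]) - o});
      }
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    const char* a = text.data() + qs;
    size_t i = 0;
    while (i < cand.size()) {
      const int rid = cand[i].first;
      // per-reference best accepted alignment across diagonal clusters
      bool have = false;
      int best_len = -1, best_d = 0;
      double best_ident = -1.0;
      size_t j = i;
      while (j < cand.size() && cand[j].first == rid) {
        // one cluster: consecutive diagonals within `band` of the previous
        size_t c0 = j;
        while (j + 1 < cand.size() && cand[j + 1].first == rid &&
               cand[j + 1].second - cand[j].second <= band)
          ++j;
        ++j;
        ++n_candidates;
        const int d = cand[c0 + (j - c0) / 2].second;  // median diagonal
        const int rl = read_len[rid];
        const int i0 = std::max(0, -d), i1 = std::min(ql, rl - d);
        const int w = i1 - i0;
        if (w <= 0) continue;
        const char* b = text.data() + read_start[rid];
        const int max_err = (int) std::ceil((1.0 - min_id / 100.0) * w);
        if (!qgram_pass_core(a + i0, w, b + i0 + d, w, q, max_err))
          continue;
        ovl_aln res = banded_overlap_core(a, ql, b, rl, d, band);
        if (!res.ok) continue;
        const int alen = res.columns;
        const double ident = (100.0 * res.matches) / res.columns;
        if (alen < min_len || ident < min_id) continue;
        if (!have || alen > best_len ||
            (alen == best_len && ident > best_ident) ||
            (alen == best_len && ident == best_ident && d < best_d)) {
          have = true; best_len = alen; best_ident = ident; best_d = d;
        }
      }
      if (have) {
        out_q.push_back(qid); out_r.push_back(rid);
        out_len.push_back(best_len); out_id.push_back(best_ident);
      }
      i = j;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("query_id") = out_q, Rcpp::Named("ref_id") = out_r,
      Rcpp::Named("alignment_length") = out_len,
      Rcpp::Named("identity") = out_id,
      Rcpp::Named("n_candidates") = (double) n_candidates);
}
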