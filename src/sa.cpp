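#include <Rcpp.h>
#include <string>
#include <vector>

// Prefix-doubling suffix array construction (Larsson-Sadakane style,
// two counting-sort passes per doubling round; O(n log n) total).
// Returns 0-based suffix start positions in lexicographic order of suffixes,
// comparing bytes as unsigned chars (C locale).
// [[Rcpp::export(name = ".sa_build_cpp")]]
Rcpp::IntegerVector sa_build_cpp(const std::string& text) {
  const int n = (int) text.size();
  if (n == 0) Rcpp::stop("text must be non-empty");
  std::vector<int> sa(n), sa2(n), r(n), nr(n);
  for (int i = 0; i < n; ++i) r[i] = (unsigned char) text[i];
  const int K = std::max(n, 256) + 2;
  std::vector<int> cnt(K);
  for (int len = 1;; len <<= 1) {
    // second key: rank of suffix i+len (+1 so that "past end" sorts first as 0)
    auto key2 = [&](int i) { return i + len < n ? r[i + len] + 1 : 0; };
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[key2(i)]++;
    for (int i = 1; i < K; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) sa2[--cnt[key2(i)]] = i;
    // stable counting sort of sa2 by first key
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[r[i]]++;
    for (int i = 1; i < K; ++i) cnt[i] += cnt[i - 1];
    for (int t = n - 1; t >= 0; --t) sa[--cnt[r[sa2[t]]]] = sa2[t];
    // re-rank
    nr[sa[0]] = 0;
    for (int t = 1; t < n; ++t) {
      const int a = sa[t], b = sa[t - 1];
      nr[a] = nr[b] + ((r[a] != r[b] || key2(a) != key2(b)) ? 1 : 0);
    }
    r = nr;
    if (r[sa[n - 1]] == n - 1) break;
  }
  return Rcpp::IntegerVector(sa.begin(), sa.end());
}

// Compare pattern against the length-|pat| prefix of the suffix at pos.
// Returns <0, 0, >0 like strcmp; a suffix shorter than pat compares smaller.
static inline int suffix_cmp(const std::string& text, int pos,
                             const std::string& pat) {
  const int n = (int) text.size(), m = (int) pat.size();
  for (int i = 0; i < m; ++i) {
    if (pos + i >= n) return -1;
    const unsigned char a = (unsigned char) text[pos + i];
    const unsigned char b = (unsigned char) pat[i];
    if (a != b) return a < b ? -1 : 1;
  }
  return 0;
}

// Half-open interval [lo, hi) of suffix-array entries whose suffixes start
// with pat; 0-based. Empty interval when pat does not occur.
// [[Rcpp::export(name = ".sa_range_cpp")]]
Rcpp::IntegerVector sa_range_cpp(const std::string& text,
                                 const Rcpp::IntegerVector& sa,
                                 const std::string& pat) {
  const int n = sa.size();
  int lo = 0, hi = n;
  while (lo < hi) {  // first suffix >= pat
    const int mid = lo + (hi - lo) / 2;
    if (suffix_cmp(text, sa[mid], pat) < 0) lo = mid + 1; else hi = mid;
  }
  const int start = lo;
  hi = n;
  while (lo < hi) {  // first suffix > pat-prefix
    const int mid = lo + (hi - lo) / 2;
    if (suffix_cmp(text, sa[mid], pat) <= 0) lo = mid + 1; else hi = mid;
  }
  return Rcpp::IntegerVector::create(start, lo);
}
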