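#ifndef OVLCOARSE_INTERNAL_H
#define OVLCOARSE_INTERNAL_H

#include <vector>

// result of one banded overlap alignment
struct ovl_aln {
  int score, columns, matches;
  int a0, a1, b0, b1;  // 0-based half-open aligned intervals
  bool ok;
};

// banded overlap DP on raw sequence pointers; see align.cpp
ovl_aln banded_overlap_core(const char* a, int la, const char* b, int lb,
                            int d, int band);

// multiset q-gram intersection count >= w + 1 - q*(e+1) ?
bool qgram_pass_core(const char* a, int la, const char* b, int lb,
                     int q, int max_errors);

#endif
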