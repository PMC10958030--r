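#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

// Locate the best occurrence of a fixed 5'-junction pattern near the start of
// each read.  The match may start anywhere in the read (the variable-length
// balancer occupies the first few bases) but must END at or before `window`.
//
// edit mode:    semi-global alignment (unit-cost substitutions + indels) of
//               the whole pattern against the read prefix; the read prefix
//               before the match and the read suffix after it are free.
// hamming mode: contiguous (ungapped) placement, substitutions only.
//
// Ties are broken by fewest errors first, then by the smallest match end.
// 'N' in the read never matches a pattern base.
//
// Returns an n x 2 integer matrix: column 1 = 1-based offset of the last
// matched read base (so trimming removes bases 1..end), column 2 = number of
// errors.  end = NA when no placement satisfies the error budget.

// [[Rcpp::export]]
IntegerMatrix cpp_locate_round1(CharacterVector reads, std::string pattern,
                                int max_err, int window, bool edit) {
  const int n = reads.size();
  const int m = (int)pattern.size();
  IntegerMatrix out(n, 2);
  std::vector<int> prev, cur;

  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    const int len = (int)std::strlen(r);
    const int w = std::min(window, len);
    int best_err = max_err + 1, best_end = NA_INTEGER;

    if (w >= 1 && m >= 1) {
      if (edit) {
        prev.assign(w + 1, 0);  // row i = 0: empty pattern, free read prefix
        cur.assign(w + 1, 0);
        for (int pi = 1; pi <= m; ++pi) {
          cur[0] = pi;
          const char pc = pattern[pi - 1];
          for (int j = 1; j <= w; ++j) {
            const char rc = r[j - 1];
            int sub = prev[j - 1] + ((rc == pc && rc != 'N') ? 0 : 1);
            int del = prev[j] + 1;      // pattern base absent from read
            int ins = cur[j - 1] + 1;   // extra read base inside the match
            cur[j] = std::min(sub, std::min(del, ins));
          }
          std::swap(prev, cur);
        }
        // prev now holds edit distances for matches ending at read base j
        for (int j = 1; j <= w; ++j) {
          if (prev[j] < best_err) { best_err = prev[j]; best_end = j; }
        }
      } else {
        for (int o = 0; o + m <= w; ++o) {
          int mm = 0;
          for (int j = 0; j < m && mm <= max_err; ++j) {
            const char rc = r[o + j];
            if (rc != pattern[j] || rc == 'N') ++mm;
          }
          if (mm < best_err) { best_err = mm; best_end = o + m; }
        }
      }
    }

    if (best_err <= max_err) {
      out(i, 0) = best_end;
      out(i, 1) = best_err;
    } else {
      out(i, 0) = NA_INTEGER;
      out(i, 1) = NA_INTEGER;
    }
  }
  return out;
}
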