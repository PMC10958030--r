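#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Seed-and-extend read mapper used for junction recovery.
//
// The reference set is expected to contain both oriented copies of every
// chromosome (forward and "_rc"), so all alignments are reported in the
// forward orientation of an oriented entry, mirroring a FLAG = 0 filter on a
// doubled reference.  Seeds are exact k-mers (2-bit encoded, k <= 31); each
// candidate diagonal is extended ungapped over the full read and scored by
// Hamming mismatches ('N' counts as a mismatch; k-mers containing non-ACGT
// bases are never seeds).  A read is reported only when its best placement is
// within the mismatch budget floor(max_mm_rate * read_len) and, when
// require_unique is true, strictly better than the second-best placement.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs, int k,
                   double max_mm_rate, bool require_unique, int min_read_len) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
  const int n_ref = refs.size();

  // concatenate references, remember entry boundaries
  std::vector<int64_t> ref_start(n_ref), ref_len(n_ref);
  int64_t total = 0;
  for (int i = 0; i < n_ref; ++i) {
    ref_len[i] = (int64_t)std::strlen(CHAR(STRING_ELT(refs, i)));
    ref_start[i] = total;
    total += ref_len[i];
  }
  std::string cat;
  cat.reserve((size_t)total);
  for (int i = 0; i < n_ref; ++i) cat.append(CHAR(STRING_ELT(refs, i)));

  // k-mer index over every entry (positions are global offsets into `cat`)
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<uint32_t>> index;
  index.reserve((size_t)total);
  for (int i = 0; i < n_ref; ++i) {
    uint64_t km = 0;
    int run = 0;  // length of current valid (ACGT) suffix
    for (int64_t p = 0; p < ref_len[i]; ++p) {
      int c = base_code(cat[(size_t)(ref_start[i] + p)]);
      if (c < 0) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[km].push_back((uint32_t)(ref_start[i] + p - k + 1));
    }
  }

  std::vector<int> o_read, o_ref, o_pos, o_mm, o_len;
  std::vector<int64_t> cand;
  const int n_reads = reads.size();

  for (int ri = 0; ri < n_reads; ++ri) {
    const char *rd = CHAR(STRING_ELT(reads, ri));
    const int len = (int)std::strlen(rd);
    if (len < min_read_len || len < k) continue;
    const int budget = (int)std::floor(max_mm_rate * len);

    cand.clear();
    uint64_t km = 0;
    int run = 0;
    for (int j = 0; j < len; ++j) {
      int c = base_code(rd[j]);
      if (c < 0) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto it = index.find(km);
        if (it != index.end()) {
          const int off = j - k + 1;  // 0-based k-mer start within read
          for (uint32_t g : it->second) cand.push_back((int64_t)g - off);
        }
      }
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    int best1 = budget + 1, best2 = budget + 1;
    int best_ref = -1;
    int64_t best_off = -1;
    for (int64_t c : cand) {
      if (c < 0 || c + len > total) continue;
      // locate containing entry; candidates spanning entries are invalid
      int e = (int)(std::upper_bound(ref_start.begin(), ref_start.end(), c) -
                    ref_start.begin()) - 1;
      if (c + len > ref_start[e] + ref_len[e]) continue;
      int mm = 0;
      const char *rs = cat.data() + c;
      for (int j = 0; j < len; ++j) {
        if (rd[j] != rs[j] || rd[j] == 'N') {
          if (++mm > budget) break;
        }
      }
      if (mm < best1) {
        best2 = best1;
        best1 = mm;
        best_ref = e;
        best_off = c;
      } else if (mm < best2) {
        best2 = mm;
      }
    }

    if (best1 <= budget && (!require_unique || best1 < best2)) {
      o_read.push_back(ri + 1);
      o_ref.push_back(best_ref + 1);
      o_pos.push_back((int)(best_off - ref_start[best_ref] + 1));
      o_mm.push_back(best1);
      o_len.push_back(len);
    }
  }

  return List::create(_["read_idx"] = wrap(o_read), _["ref_idx"] = wrap(o_ref),
                      _["pos"] = wrap(o_pos), _["mismatches"] = wrap(o_mm),
                      _["mapped_len"] = wrap(o_len));
}
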