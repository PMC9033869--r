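#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode; -1 for non-ACGT
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Count canonical k-mers (lexicographic min of word and reverse complement)
// over every clean length-k window of every sequence; windows containing a
// non-ACGT symbol are skipped. Returns the multiplicity histogram as a
// named numeric vector: names are multiplicities, values are the number of
// distinct canonical k-mers at that multiplicity.
// [[Rcpp::export]]
NumericVector cpp_kmer_histogram(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (; *p; ++p) {
      int b = base2bits(*p);
      if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
      }
    }
  }

  std::unordered_map<uint32_t, double> hist;
  for (const auto& kv : counts) ++hist[kv.second];
  std::vector<uint32_t> mult;
  mult.reserve(hist.size());
  for (const auto& kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());

  NumericVector out(mult.size());
  CharacterVector nm(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    out[i] = hist[mult[i]];
    nm[i] = std::to_string(mult[i]);
  }
  out.attr("names") = nm;
  return out;
}
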