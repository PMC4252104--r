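#ifndef PEGASM_COMMON_H
#define PEGASM_COMMON_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>

// 2-bit base codes: A=0, C=1, G=2, T=3; anything else (N, ...) = -1.
inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline char code_base(int c) { return "ACGT"[c & 3]; }

inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

inline std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Encode k-mer starting at s[pos]; returns false if any non-ACGT base.
inline bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

inline uint64_t revcomp_code(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

// One sampled k-mer occurrence on a read.  `read` is the global read index
// (2*pair + mate, 0-based), `pos` the 0-based k-mer start on the read as
// sequenced, `strand` 0 if the read's own k-mer equals the canonical key,
// 1 if its reverse complement does.
struct Occ {
  int32_t read;
  int32_t pos;
  uint8_t strand;
};

class KmerIndex {
public:
  int k;
  double sample_fraction;
  std::vector<std::string> reads;  // global read index -> sequence
  std::unordered_map<uint64_t, std::vector<Occ>> table;

  int n_reads() const { return (int)reads.size(); }
  const std::string& read_seq(int r) const { return reads[r]; }
  int mate_of(int r) const { return r ^ 1; }

  int freq(uint64_t canon_key) const {
    auto it = table.find(canon_key);
    return it == table.end() ? 0 : (int)it->second.size();
  }
};

#endif
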