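#include "asm_common.h"
using namespace Rcpp;

// Sampled k-mer start positions for a read of length L: with fraction f < 1,
// the ceil(f/2 * (L-k+1)) positions closest to each end (duplicates removed);
// with f >= 1 every position.
static std::vector<int> sampled_positions(int L, int k, double f) {
  std::vector<int> out;
  int np = L - k + 1;
  if (np <= 0) return out;
  if (f >= 1.0) {
    for (int i = 0; i < np; ++i) out.push_back(i);
    return out;
  }
  int m = (int)std::ceil(0.5 * f * np);
  if (m < 1) m = 1;
  std::vector<bool> take(np, false);
  for (int i = 0; i < m && i < np; ++i) take[i] = true;
  for (int i = 0; i < m && i < np; ++i) take[np - 1 - i] = true;
  for (int i = 0; i < np; ++i) if (take[i]) out.push_back(i);
  return out;
}

// [[Rcpp::export]]
SEXP idx_build(CharacterVector seq1, CharacterVector seq2, int k,
               double sample_fraction) {
  if (seq1.size() != seq2.size())
    stop("mate vectors differ in length");
  if (k < 1 || k > 31) stop("k must be in 1..31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->sample_fraction = sample_fraction;
  idx->reads.reserve(2 * seq1.size());
  for (R_xlen_t p = 0; p < seq1.size(); ++p) {
    idx->reads.push_back(as<std::string>(seq1[p]));
    idx->reads.push_back(as<std::string>(seq2[p]));
  }
  for (int r = 0; r < idx->n_reads(); ++r) {
    const std::string& s = idx->reads[r];
    if ((int)s.size() < k) continue;
    for (int pos : sampled_positions((int)s.size(), k, sample_fraction)) {
      uint64_t code;
      if (!encode_kmer(s, pos, k, code)) continue;  // k-mers spanning N skipped
      uint64_t rc = revcomp_code(code, k);
      uint64_t key = code <= rc ? code : rc;
      Occ o;
      o.read = r;
      o.pos = pos;
      o.strand = (code <= rc) ? 0 : 1;
      idx->table[key].push_back(o);
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List idx_info(SEXP idxp) {
  XPtr<KmerIndex> idx(idxp);
  size_t nocc = 0;
  for (auto& kv : idx->table) nocc += kv.second.size();
  return List::create(_["k"] = idx->k,
                      _["n_pairs"] = idx->n_reads() / 2,
                      _["n_keys"] = (double)idx->table.size(),
                      _["n_occurrences"] = (double)nocc,
                      _["sample_fraction"] = idx->sample_fraction);
}

// [[Rcpp::export]]
DataFrame idx_lookup(SEXP idxp, std::string kmer) {
  XPtr<KmerIndex> idx(idxp);
  if ((int)kmer.size() != idx->k) stop("query length != k");
  uint64_t code;
  if (!encode_kmer(kmer, 0, idx->k, code)) stop("non-ACGT base in query");
  uint64_t rc = revcomp_code(code, idx->k);
  uint64_t key = code <= rc ? code : rc;
  std::vector<int> read, mate, pos;
  std::vector<std::string> strand;
  auto it = idx->table.find(key);
  if (it != idx->table.end()) {
    for (const Occ& o : it->second) {
      read.push_back(o.read / 2 + 1);
      mate.push_back(o.read % 2 + 1);
      pos.push_back(o.pos);
      strand.push_back(o.strand == 0 ? "+" : "-");
    }
  }
  return DataFrame::create(_["read_id"] = read, _["mate"] = mate,
                           _["pos"] = pos, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
int idx_freq(SEXP idxp, std::string kmer) {
  XPtr<KmerIndex> idx(idxp);
  uint64_t code;
  if (!encode_kmer(kmer, 0, idx->k, code)) return 0;
  uint64_t rc = revcomp_code(code, idx->k);
  return idx->freq(code <= rc ? code : rc);
}

// [[Rcpp::export]]
std::string cpp_canonical(std::string kmer) {
  uint64_t code;
  if (kmer.size() < 1 || kmer.size() > 31)
    stop("k-mer length must be in 1..31");
  if (!encode_kmer(kmer, 0, (int)kmer.size(), code))
    stop("non-ACGT base in k-mer");
  uint64_t rc = revcomp_code(code, (int)kmer.size());
  if (rc < code) return revcomp(kmer);
  std::string up(kmer);
  for (auto& c : up) c = toupper(c);
  return up;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// Longest run of consecutive k-mers shared by two reads along one diagonal
// (plain, same-strand comparison).  Two reads overlapping error-free over w
// bases share w - k + 1 consecutive k-mers.
// [[Rcpp::export]]
int cpp_shared_consecutive(std::string a, std::string b, int k) {
  int na = (int)a.size() - k + 1, nb = (int)b.size() - k + 1;
  if (na < 1 || nb < 1) return 0;
  int best = 0;
  // dp over diagonals: run length of consecutive equal k-mers
  for (int d = -(nb - 1); d <= na - 1; ++d) {
    int run = 0;
    for (int i = std::max(0, d); i < na && i - d < nb; ++i) {
      int j = i - d;
      if (a.compare(i, k, b, j, k) == 0) {
        if (++run > best) best = run;
      } else run = 0;
    }
  }
  return best;
}
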