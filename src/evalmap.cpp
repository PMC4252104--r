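#include "asm_common.h"
using namespace Rcpp;

// Banded Levenshtein distance (unit costs).  Suited to substitution-
// dominated comparisons; band caps the indel offset considered.
static int banded_dist(const std::string& a, const std::string& b, int band) {
  int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > band) band = std::abs(n - m) + band;
  const int INF = 1 << 28;
  std::vector<int> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  // column j for row i lives at index j - i + band
  prev[band] = 0;
  for (int j = 1; j <= std::min(m, band); ++j) prev[band + j] = j;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int idx = j - i + band;
      int best = INF;
      if (j > 0 && j - 1 - i + band >= 0)
        best = std::min(best, cur[j - 1 - i + band] + 1);  // insertion
      if (j - (i - 1) + band <= 2 * band)
        best = std::min(best, prev[j - (i - 1) + band] + 1);  // deletion
      if (j > 0) {
        int d = prev[j - 1 - (i - 1) + band];
        best = std::min(best, d + (a[i - 1] == b[j - 1] ? 0 : 1));
      }
      if (j == 0) best = std::min(best, i);
      cur[idx] = best;
    }
    prev.swap(cur);
  }
  int r = prev[m - n + band];
  return r >= INF ? std::max(n, m) : r;
}

// [[Rcpp::export]]
int cpp_banded_dist(std::string a, std::string b, int band) {
  return banded_dist(a, b, band);
}

// Largest suffix(a)/prefix(b) overlap with at most max_mm_frac mismatches.
// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b, int max_ov,
                      double max_mm_frac) {
  int lim = std::min<int>(std::min(a.size(), b.size()), max_ov);
  for (int ov = lim; ov >= 1; --ov) {
    int mm = 0;
    int budget = (int)std::floor(max_mm_frac * ov);
    size_t as = a.size() - ov;
    bool ok = true;
    for (int i = 0; i < ov; ++i) {
      if (a[as + i] != b[i] && ++mm > budget) { ok = false; break; }
    }
    if (ok) return List::create(_["len"] = ov, _["mm"] = mm);
  }
  return List::create(_["len"] = 0, _["mm"] = 0);
}

// Map assembly records onto a reference by canonical k-mer anchoring plus
// banded global alignment of the whole record at its best anchor.
// Returns, per record: best anchor start (0-based), strand, similarity,
// and all anchored intervals (diagonal clusters with >= min_hits hits).
// [[Rcpp::export]]
List eval_map(CharacterVector records, std::string ref, int k, int min_hits,
              int band) {
  long G = (long)ref.size();
  std::unordered_map<uint64_t, std::vector<int32_t>> rmap;
  for (long p = 0; p + k <= G; ++p) {
    uint64_t code;
    if (!encode_kmer(ref, p, k, code)) continue;
    auto& v = rmap[code];
    if ((int)v.size() < 200) v.push_back((int32_t)p);
  }
  List out(records.size());
  for (R_xlen_t ri = 0; ri < records.size(); ++ri) {
    std::string rec = as<std::string>(records[ri]);
    int n = (int)rec.size();
    int step = std::max(1, n / 400);
    // hits: (strand, diag) where diag = ref position of oriented record pos 0
    std::vector<std::pair<int64_t, int>> hits;  // (diag, strand)
    for (int i = 0; i + k <= n; i += step) {
      uint64_t code;
      if (!encode_kmer(rec, i, k, code)) continue;
      auto it = rmap.find(code);
      if (it != rmap.end())
        for (int32_t p : it->second) hits.push_back({(int64_t)p - i, 0});
      uint64_t rc = revcomp_code(code, k);
      auto it2 = rmap.find(rc);
      if (it2 != rmap.end())
        for (int32_t p : it2->second)
          hits.push_back({(int64_t)p - (n - k - i), 1});
    }
    // cluster by strand then diagonal (tolerance = band)
    std::vector<std::tuple<int, int64_t, int>> clusters;  // hits, diag, strand
    for (int st = 0; st < 2; ++st) {
      std::vector<int64_t> ds;
      for (auto& h : hits)
        if (h.second == st) ds.push_back(h.first);
      std::sort(ds.begin(), ds.end());
      size_t i = 0;
      while (i < ds.size()) {
        size_t j = i;
        while (j + 1 < ds.size() && ds[j + 1] - ds[j] <= band) ++j;
        int cnt = (int)(j - i + 1);
        int64_t mid = ds[i + (j - i) / 2];
        if (cnt >= min_hits) clusters.push_back({cnt, mid, st});
        i = j + 1;
      }
    }
    if (clusters.empty()) {
      out[ri] = List::create(_["start"] = NA_INTEGER, _["strand"] = NA_STRING,
                             _["similarity"] = 0.0,
                             _["intervals"] = IntegerMatrix(0, 2));
      continue;
    }
    std::sort(clusters.begin(), clusters.end(),
              [](const std::tuple<int, int64_t, int>& x,
                 const std::tuple<int, int64_t, int>& y) {
                return std::get<0>(x) > std::get<0>(y);
              });
    IntegerMatrix iv((int)clusters.size(), 2);
    for (size_t ci = 0; ci < clusters.size(); ++ci) {
      int64_t d = std::get<1>(clusters[ci]);
      int64_t s = std::max<int64_t>(0, d);
      int64_t e = std::min<int64_t>(G, d + n);
      iv(ci, 0) = (int)s;
      iv(ci, 1) = (int)e;
    }
    int64_t bd = std::get<1>(clusters[0]);
    int bst = std::get<2>(clusters[0]);
    std::string orec = bst == 0 ? rec : revcomp(rec);
    int64_t ws = std::max<int64_t>(0, bd);
    int64_t we = std::min<int64_t>(G, bd + n);
    std::string win = ref.substr(ws, we - ws);
    int dist = banded_dist(orec, win, band);
    double sim = 1.0 - (double)dist / std::max<int>(n, (int)win.size());
    out[ri] = List::create(
        _["start"] = (int)ws,
        _["strand"] = bst == 0 ? "+" : "-",
        _["similarity"] = sim, _["intervals"] = iv);
  }
  return out;
}

// For each context string: occurrences in the truth sequence (both strands)
// and the set of possible continuation symbols ('$' marks the sequence end).
// [[Rcpp::export]]
List cpp_truth_next(std::string truth, CharacterVector contexts) {
  List out(contexts.size());
  for (R_xlen_t i = 0; i < contexts.size(); ++i) {
    std::string c = as<std::string>(contexts[i]);
    std::string crc = revcomp(c);
    int n_occ = 0;
    std::set<char> nxt;
    size_t pos = truth.find(c, 0);
    while (pos != std::string::npos) {
      ++n_occ;
      size_t after = pos + c.size();
      nxt.insert(after < truth.size() ? truth[after] : '$');
      pos = truth.find(c, pos + 1);
    }
    pos = truth.find(crc, 0);
    while (pos != std::string::npos) {
      ++n_occ;
      nxt.insert(pos > 0 ? comp_base(truth[pos - 1]) : '$');
      pos = truth.find(crc, pos + 1);
    }
    std::string syms(nxt.begin(), nxt.end());
    out[i] = List::create(_["n_occ"] = n_occ, _["next"] = syms);
  }
  return out;
}
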