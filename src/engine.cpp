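#include "asm_common.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Run configuration (validated on the R side; parsed verbatim here)
// ---------------------------------------------------------------------------
struct Cfg {
  int k, Omin, Omax;
  double sample_fraction;
  double min_similarity;   // whole-overlap similarity for read acceptance
  double min_align_frac;   // fraction of overlapped bases that must match
  int max_bubble;          // longest tolerated mismatch run (= Omin)
  double path_majority;    // look-ahead per-column majority threshold
  int max_bad_positions;   // look-ahead low-majority column limit
  int min_path_overlap;    // tandem path suffix/prefix overlap (strict >)
  int min_contig_merge_overlap;
  double insert_sd_mult;
  int min_contig_len;
  int low_freq_threshold;  // seed k-mer frequency must strictly exceed this
  int min_pairs_paired;    // pairs needed for a decidable paired tally
  int min_branch_support;  // second-base support needed to call a branch
  int min_insert_n;        // observed pairs before the insert model is used
  double heur_ratio;       // secOcc/maxOcc cutoff of the fallback heuristic
  int heur_gap;            // gapLen cutoff of the fallback heuristic
  double heur_cov;         // covRatio cap for a confident heuristic continue
  int nav_mode;            // 0 majority, 1 heuristic, 2 svm
  int max_contig_len;
  int linking_region;
  int trace_context;

  static Cfg parse(List c) {
    Cfg f;
    f.k = as<int>(c["k"]);
    f.Omin = as<int>(c["O_min"]);
    f.Omax = as<int>(c["O_max"]);
    f.sample_fraction = as<double>(c["sample_fraction"]);
    f.min_similarity = as<double>(c["min_similarity"]);
    f.min_align_frac = as<double>(c["min_align_frac"]);
    f.max_bubble = f.Omin;
    f.path_majority = as<double>(c["path_majority"]);
    f.max_bad_positions = as<int>(c["max_bad_positions"]);
    f.min_path_overlap = as<int>(c["min_path_overlap"]);
    f.min_contig_merge_overlap = as<int>(c["min_contig_merge_overlap"]);
    f.insert_sd_mult = as<double>(c["insert_sd_mult"]);
    f.min_contig_len = as<int>(c["min_contig_len"]);
    f.low_freq_threshold = as<int>(c["low_freq_threshold"]);
    f.min_pairs_paired = as<int>(c["min_pairs_paired"]);
    f.min_branch_support = as<int>(c["min_branch_support"]);
    f.min_insert_n = as<int>(c["min_insert_n"]);
    f.heur_ratio = as<double>(c["heur_ratio"]);
    f.heur_gap = as<int>(c["heur_gap"]);
    f.heur_cov = as<double>(c["heur_cov"]);
    std::string nm = as<std::string>(c["navigation"]);
    f.nav_mode = nm == "majority" ? 0 : (nm == "heuristic" ? 1 : 2);
    f.max_contig_len = as<int>(c["max_contig_len"]);
    f.linking_region = as<int>(c["linking_region"]);
    f.trace_context = as<int>(c["trace_context"]);
    return f;
  }
};

// Trained navigator for one feature mode, applied through the dual expansion
// decision(x) = sum_i coef_i * Kp(sv_i, z) + rho with z the standardized
// feature vector and Kp(u,v) = <u,v> * (1 + <u,v>)^2.
struct SvmM {
  bool has = false;
  std::vector<std::array<double, 4>> sv;
  std::vector<double> coef;
  double rho = 0, margin = 0.5;
  double center[4] = {0, 0, 0, 0}, scale[4] = {1, 1, 1, 1};

  static SvmM parse(SEXP x, double fallback_margin) {
    SvmM m;
    m.margin = fallback_margin;
    if (Rf_isNull(x)) return m;
    List l(x);
    NumericMatrix svm_ = l["sv"];
    NumericVector co = l["coef"];
    m.rho = as<double>(l["rho"]);
    m.margin = as<double>(l["margin"]);
    NumericVector ce = l["center"], sc = l["scale"];
    for (int j = 0; j < 4; ++j) {
      m.center[j] = ce[j];
      m.scale[j] = sc[j] > 0 ? sc[j] : 1.0;
    }
    for (int i = 0; i < svm_.nrow(); ++i) {
      std::array<double, 4> v;
      for (int j = 0; j < 4; ++j) v[j] = svm_(i, j);
      m.sv.push_back(v);
      m.coef.push_back(co[i]);
    }
    m.has = true;
    return m;
  }

  double decision(const double* feat) const {
    double z[4];
    for (int j = 0; j < 4; ++j) z[j] = (feat[j] - center[j]) / scale[j];
    double d = rho;
    for (size_t i = 0; i < sv.size(); ++i) {
      double dot = 0;
      for (int j = 0; j < 4; ++j) dot += sv[i][j] * z[j];
      d += coef[i] * dot * (1 + dot) * (1 + dot);
    }
    return d;
  }
};

// Active (partial) alignment record at the extending 3' end.
struct ARec {
  int32_t read;
  int32_t off;      // contig offset of the read's oriented start
  uint8_t strand;   // 0: read matches contig; 1: contig matches revcomp(read)
  int32_t matched, mm, mm_run;
};

struct FRec {
  int32_t read;
  int32_t off;
  uint8_t strand;
};

static inline int64_t rec_key(int32_t read, int32_t off) {
  return ((int64_t)read << 32) | (uint32_t)off;
}

// ---------------------------------------------------------------------------
// Extension engine
// ---------------------------------------------------------------------------
class Engine {
public:
  KmerIndex* idx;
  Cfg cfg;
  SvmM svm_paired, svm_single;
  Function* la_cb = nullptr;
  bool use_lookahead = false;
  int rl;  // typical read length

  std::vector<uint8_t> used, tried_seed;

  // per-contig state
  std::string S;
  std::vector<ARec> act;
  std::vector<FRec> fullv;
  std::unordered_map<int32_t, int32_t> full_by_read;
  std::vector<int32_t> support;
  std::unordered_set<int64_t> active_key, rejected;
  long last_full_end = 0;

  // global insert-size model (pairs with both mates fully aligned, inward)
  double is_sum = 0, is_sum2 = 0;
  int is_n = 0;

  // decision trace
  std::vector<int> tr_contig, tr_at, tr_pass, tr_O, tr_maxOcc, tr_secOcc,
      tr_gapLen;
  std::vector<double> tr_covRatio, tr_decval;
  std::vector<std::string> tr_mode, tr_stage, tr_action, tr_base, tr_context;
  int cur_contig = 0, cur_pass = 1;

  Engine(KmerIndex* i, const Cfg& c) : idx(i), cfg(c) {
    used.assign(idx->n_reads(), 0);
    tried_seed.assign(idx->n_reads(), 0);
    rl = 0;
    for (int r = 0; r < idx->n_reads(); ++r)
      rl = std::max<int>(rl, (int)idx->reads[r].size());
    if (rl == 0) rl = 100;
  }

  void set_insert_prior(double mean, double sd, int n) {
    if (n > 0) {
      is_n = n;
      is_sum = mean * n;
      is_sum2 = (n > 1 ? sd * sd * (n - 1) : 0) + mean * mean * n;
    }
  }
  double ins_mean() const { return is_n > 0 ? is_sum / is_n : 0; }
  double ins_sd() const {
    if (is_n < 2) return 0;
    double v = (is_sum2 - is_sum * is_sum / is_n) / (is_n - 1);
    return v > 0 ? std::sqrt(v) : 0;
  }

  int rlen(int r) const { return (int)idx->reads[r].size(); }

  // oriented base of read r (strand st) at offset q along the contig
  char obase(int r, uint8_t st, int q) const {
    const std::string& s = idx->reads[r];
    return st == 0 ? s[q] : comp_base(s[s.size() - 1 - q]);
  }

  void reset_contig(const std::string& seed) {
    S = seed;
    act.clear();
    fullv.clear();
    full_by_read.clear();
    support.assign(S.size(), 0);
    active_key.clear();
    rejected.clear();
    last_full_end = 0;
  }

  // Similarity rules for accepting an aligned span: >=90% of overlapped
  // bases match, overall similarity >= 95%, no mismatch run longer than
  // O_min (bubble limit).
  bool span_ok(int matched, int ov, int mm_run) const {
    if (ov <= 0) return false;
    double sim = (double)matched / ov;
    return sim >= cfg.min_align_frac - 1e-9 &&
           sim >= cfg.min_similarity - 1e-9 && mm_run <= cfg.max_bubble;
  }

  // verify read r (strand st) at offset off against base accessor over
  // positions [off, lim); returns matched/mm/max run
  template <class BaseAt>
  bool verify(int r, uint8_t st, int32_t off, long lim, BaseAt base_at,
              int& matched, int& mm, int& run_out) const {
    int L = rlen(r);
    long end = std::min<long>(lim, (long)off + L);
    matched = 0;
    mm = 0;
    int run = 0, maxrun = 0;
    for (long p = off; p < end; ++p) {
      if (obase(r, st, (int)(p - off)) == base_at(p)) {
        ++matched;
        run = 0;
      } else {
        ++mm;
        if (++run > maxrun) maxrun = run;
      }
    }
    run_out = run;  // trailing mismatch run (0 if last base matched)
    int ov = (int)(end - off);
    return span_ok(matched, ov, maxrun);
  }

  void accept_full(int32_t read, int32_t off, uint8_t strand) {
    used[read] = 1;
    FRec f{read, off, strand};
    full_by_read[read] = (int)fullv.size();
    fullv.push_back(f);
    int L = rlen(read);
    for (int p = std::max(0, off); p < std::min<int>((int)S.size(), off + L);
         ++p)
      ++support[p];
    last_full_end = std::max(last_full_end, (long)off + L);
    // insert model update when the mate is also fully aligned, inward
    int m = idx->mate_of(read);
    auto it = full_by_read.find(m);
    if (it != full_by_read.end()) {
      const FRec& mf = fullv[it->second];
      const FRec& me = fullv[full_by_read[read]];
      const FRec& fwd = me.strand == 0 ? me : mf;
      const FRec& rev = me.strand == 0 ? mf : me;
      if (fwd.strand == 0 && rev.strand == 1 && fwd.off <= rev.off) {
        double span = (double)rev.off + rlen(rev.read) - fwd.off;
        is_sum += span;
        is_sum2 += span * span;
        ++is_n;
      }
    }
  }

  // Try to place one occurrence implied at offset `off`; contig-only version
  void try_place(int32_t read, uint8_t strand, int32_t off) {
    if (off < 0 || used[read]) return;
    int64_t key = rec_key(read, off);
    if (active_key.count(key) || rejected.count(key)) return;
    if (full_by_read.count(read)) return;
    int L = rlen(read);
    long len = (long)S.size();
    int matched, mm, run;
    const std::string& Sref = S;
    bool ok = verify(read, strand, off, len, [&](long p) { return Sref[p]; },
                     matched, mm, run);
    if (!ok) {
      rejected.insert(key);
      return;
    }
    if ((long)off + L <= len) {
      accept_full(read, off, strand);
    } else {
      act.push_back(ARec{read, off, strand, matched, mm, run});
      active_key.insert(key);
    }
  }

  // place all index occurrences of the k-mer at contig position p
  void recruit_at(long p) {
    uint64_t code;
    if (!encode_kmer(S, p, cfg.k, code)) return;
    uint64_t rc = revcomp_code(code, cfg.k);
    uint64_t ckey = code <= rc ? code : rc;
    uint8_t q_strand = code <= rc ? 0 : 1;
    auto it = idx->table.find(ckey);
    if (it == idx->table.end()) return;
    for (const Occ& o : it->second) {
      uint8_t align_strand = (o.strand == q_strand) ? 0 : 1;
      int L = rlen(o.read);
      int pos_o = align_strand == 0 ? o.pos : L - cfg.k - o.pos;
      int32_t off = (int32_t)(p - pos_o);
      try_place(o.read, align_strand, off);
    }
  }

  void recruit_terminal() { recruit_at((long)S.size() - cfg.k); }

  // scan a window at the 3' end (used after seeding/flipping/probing)
  void recruit_window(long from) {
    long len = (long)S.size();
    for (long p = std::max<long>(0, from); p + cfg.k <= len; ++p)
      recruit_at(p);
  }

  // append chosen base and advance the active records
  void append_base(char b) {
    S.push_back(b);
    support.push_back(0);
    long len = (long)S.size();
    std::vector<ARec> keep;
    keep.reserve(act.size());
    for (ARec& a : act) {
      int L = rlen(a.read);
      int q = (int)(len - 1 - a.off);
      if (q >= L) continue;  // shouldn't happen: completed earlier
      if (obase(a.read, a.strand, q) == b) {
        ++a.matched;
        a.mm_run = 0;
      } else {
        ++a.mm;
        ++a.mm_run;
      }
      int ov = q + 1;
      if (!span_ok(a.matched, ov, a.mm_run)) {
        active_key.erase(rec_key(a.read, a.off));
        rejected.insert(rec_key(a.read, a.off));
        continue;
      }
      if (q == L - 1) {  // fully aligned now
        active_key.erase(rec_key(a.read, a.off));
        if (!used[a.read]) accept_full(a.read, a.off, a.strand);
        continue;
      }
      keep.push_back(a);
    }
    act.swap(keep);
  }

  bool paired_usable() const {
    return is_n >= cfg.min_insert_n &&
           (long)S.size() >= (long)(ins_mean() + 2 * ins_sd());
  }

  // tally over pool-1 reads with paired-end support: reverse-strand partials
  // whose mates are fully aligned forward at a compatible insert span
  void tally_paired(int cnt[4]) const {
    cnt[0] = cnt[1] = cnt[2] = cnt[3] = 0;
    double mu = ins_mean(), sd = ins_sd();
    long len = (long)S.size();
    for (const ARec& a : act) {
      if (a.strand != 1) continue;
      int L = rlen(a.read);
      int q = (int)(len - a.off);
      if (q >= L) continue;
      auto it = full_by_read.find(idx->mate_of(a.read));
      if (it == full_by_read.end()) continue;
      const FRec& mf = fullv[it->second];
      if (mf.strand != 0 || mf.off > a.off) continue;
      double span = (double)a.off + L - mf.off;
      if (std::fabs(span - mu) > cfg.insert_sd_mult * sd) continue;
      int c = base_code(obase(a.read, a.strand, q));
      if (c >= 0) ++cnt[c];
    }
  }

  void tally_single(int O, int cnt[4]) const {
    cnt[0] = cnt[1] = cnt[2] = cnt[3] = 0;
    long len = (long)S.size();
    for (const ARec& a : act) {
      int L = rlen(a.read);
      int q = (int)(len - a.off);
      if (q >= L) continue;
      if (q < O) continue;  // overlapped span with contig must reach O
      int c = base_code(obase(a.read, a.strand, q));
      if (c >= 0) ++cnt[c];
    }
  }

  void features_from(const int cnt[4], double* f) const {
    int mx = 0, sec = 0;
    for (int i = 0; i < 4; ++i) {
      if (cnt[i] >= mx) {
        sec = mx;
        mx = cnt[i];
      } else if (cnt[i] > sec)
        sec = cnt[i];
    }
    long len = (long)S.size();
    long w = std::min<long>(len, 2L * rl);
    double se = 0, sa = 0;
    for (long p = len - w; p < len; ++p) se += support[p];
    // partially aligned reads cover the extending end before they are
    // full; without them the end-window density always droops by about
    // one read length and a repeat pile-up would go unnoticed
    for (const ARec& a : act) {
      long lo = std::max<long>(a.off, len - w);
      if (lo < len) se += (double)(len - lo);
    }
    for (long p = 0; p < len; ++p) sa += support[p];
    double cov_end = w > 0 ? se / w : 0;
    double cov_all = len > 0 ? sa / len : 0;
    f[0] = mx;
    f[1] = sec;
    f[2] = cov_all > 0 ? cov_end / cov_all : 1.0;
    f[3] = std::max<long>(0, len - last_full_end);
  }

  // navigator verdict: 1 CONTINUE, 0 STOP, -1 LOW_CONFIDENCE
  int navigate(const double* f, bool paired, double& decval) const {
    decval = NA_REAL;
    if (cfg.nav_mode == 0)  // pure majority (training runs)
      return f[0] > f[1] ? 1 : 0;
    int v;
    const SvmM& m = paired ? svm_paired : svm_single;
    if (cfg.nav_mode == 2 && m.has) {
      double d = m.decision(f);
      decval = d;
      v = std::fabs(d) <= m.margin ? -1 : (d > 0 ? 1 : 0);
    } else {
      // zero-dependency heuristic fallback
      v = (f[0] > 0 && f[1] / f[0] < cfg.heur_ratio &&
           f[3] <= cfg.heur_gap && f[2] <= cfg.heur_cov) ? 1 : -1;
    }
    // a dead tie has no majority base to extend: CONTINUE is not an option
    if (v == 1 && f[0] <= f[1]) v = -1;
    return v;
  }

  std::string context() const {
    long len = (long)S.size();
    long w = std::min<long>(len, cfg.trace_context);
    return S.substr(len - w);
  }

  void trace_row(const std::string& mode, int O, const double* f,
                 const std::string& stage, const std::string& action,
                 const std::string& base, double decval) {
    tr_contig.push_back(cur_contig);
    tr_at.push_back((int)S.size());
    tr_pass.push_back(cur_pass);
    tr_mode.push_back(mode);
    tr_O.push_back(O);
    tr_maxOcc.push_back((int)f[0]);
    tr_secOcc.push_back((int)f[1]);
    tr_covRatio.push_back(f[2]);
    tr_gapLen.push_back((int)f[3]);
    tr_stage.push_back(stage);
    tr_action.push_back(action);
    tr_base.push_back(base);
    tr_decval.push_back(decval);
    tr_context.push_back(context());
  }

  // ------------------------------------------------------------------
  // Look-ahead: candidate forward paths at the current branch
  // ------------------------------------------------------------------
  struct PathRead {
    int32_t read, off;  // absolute offset in contig+path coordinates
    uint8_t strand;
    int32_t matched, mm, mm_run;
    double pspan;       // implied insert span via a contig-full mate (or -1)
    bool done;
  };

  // one candidate forward path under construction; forked at residual ties
  struct PathState {
    std::string P;
    char first, next;
    std::vector<PathRead> pr;
    std::unordered_set<int64_t> pkey, prej;
    std::vector<double> pair_d;
  };

  double path_read_span(const PathRead& a) const {
    if (a.strand != 1) return -1;
    auto it = full_by_read.find(idx->mate_of(a.read));
    if (it == full_by_read.end() || fullv[it->second].strand != 0) return -1;
    return (double)a.off + rlen(a.read) - fullv[it->second].off;
  }

  // grow one state to its end, forking into `work` at unresolved ties
  void run_path_state(PathState st, int horizon,
                      std::vector<PathState>& work,
                      std::vector<PathState>& out, int max_states) {
    long len0 = (long)S.size();
    double mu = ins_mean(), sd = ins_sd();
    bool have_ins = is_n >= cfg.min_insert_n;
    char nb = st.next;
    while ((int)st.P.size() < horizon) {
      st.P.push_back(nb);
      long len = len0 + (long)st.P.size();
      auto base_at = [&](long p) -> char {
        return p < len0 ? S[p] : st.P[p - len0];
      };
      // advance supporting reads over the appended base
      for (auto& a : st.pr) {
        if (a.done) continue;
        int L = rlen(a.read);
        int q = (int)(len - 1 - a.off);
        if (q < 0 || q >= L) continue;
        if (obase(a.read, a.strand, q) == nb) {
          ++a.matched;
          a.mm_run = 0;
        } else {
          ++a.mm;
          ++a.mm_run;
        }
        int ov = (int)(std::min<long>(len, (long)a.off + L) -
                       std::max<long>(a.off, 0));
        if (!span_ok(a.matched, ov, a.mm_run)) {
          a.done = true;
          a.matched = -1;  // rejected from this path
          continue;
        }
        if (q == L - 1) a.done = true;  // fully aligned onto contig+path
      }
      // recruit unused reads at the path terminus
      if (len >= cfg.k) {
        uint64_t code = 0;
        bool okk = true;
        for (int i = 0; i < cfg.k; ++i) {
          int c = base_code(base_at(len - cfg.k + i));
          if (c < 0) { okk = false; break; }
          code = (code << 2) | (uint64_t)c;
        }
        if (okk) {
          uint64_t rc = revcomp_code(code, cfg.k);
          uint64_t ckey = code <= rc ? code : rc;
          uint8_t q_strand = code <= rc ? 0 : 1;
          auto it = idx->table.find(ckey);
          if (it != idx->table.end()) {
            for (const Occ& o : it->second) {
              if (used[o.read]) continue;
              uint8_t rst = (o.strand == q_strand) ? 0 : 1;
              int L = rlen(o.read);
              int pos_o = rst == 0 ? o.pos : L - cfg.k - o.pos;
              int32_t off = (int32_t)(len - cfg.k - pos_o);
              if (off < 0) continue;
              int64_t key = rec_key(o.read, off);
              if (st.pkey.count(key) || st.prej.count(key)) continue;
              int matched, mm, run;
              if (verify(o.read, rst, off, len, base_at, matched, mm,
                         run)) {
                PathRead prd{o.read, off, rst, matched, mm, run, -1,
                             (long)off + L <= len};
                prd.pspan = path_read_span(prd);
                if (prd.pspan > 0) st.pair_d.push_back(prd.pspan);
                st.pr.push_back(prd);
                st.pkey.insert(key);
              } else
                st.prej.insert(key);
            }
          }
        }
      }
      // next base: paired-compatible plurality first, then all partials
      int cnt[4] = {0, 0, 0, 0}, cntp[4] = {0, 0, 0, 0};
      for (const auto& a : st.pr) {
        if (a.done || a.matched < 0) continue;
        int L = rlen(a.read);
        int q = (int)(len - a.off);
        if (q < 0 || q >= L) continue;
        int c = base_code(obase(a.read, a.strand, q));
        if (c < 0) continue;
        ++cnt[c];
        if (have_ins && a.pspan > 0 &&
            std::fabs(a.pspan - mu) <= cfg.insert_sd_mult * sd)
          ++cntp[c];
      }
      int pick = -1;
      for (const int* v : {cntp, cnt}) {
        int mx = 0, mxc = -1, nmx = 0;
        for (int c = 0; c < 4; ++c) {
          if (v[c] > mx) { mx = v[c]; mxc = c; nmx = 1; }
          else if (v[c] == mx && mx > 0) ++nmx;
        }
        if (mx > 0 && nmx == 1) { pick = mxc; break; }
        if (v == cnt && mx > 0 && nmx > 1) {
          // residual tie: fork the state for the tied alternatives
          bool taken = false;
          for (int c = 0; c < 4; ++c) {
            if (v[c] != mx) continue;
            if (!taken) { pick = c; taken = true; }
            else if ((int)(work.size() + out.size()) + 2 < max_states) {
              PathState fk = st;
              fk.next = code_base(c);
              work.push_back(std::move(fk));
            }
          }
        }
      }
      if (pick < 0) break;  // no support left
      nb = code_base(pick);
    }
    out.push_back(std::move(st));
  }

  List finish_path(const PathState& st, int horizon) {
    long len0 = (long)S.size();
    const std::string& P = st.P;
    int best_mm = -1;
    int m = (int)P.size();
    if (m > 0) {
      long lo = std::min<long>(len0, (long)m + 2L * rl);
      for (long s = m; s <= lo; ++s) {
        int mm = 0;
        for (int i = 0; i < m; ++i)
          if (S[len0 - s + i] != P[i]) ++mm;
        if (best_mm < 0 || mm < best_mm) best_mm = mm;
      }
      if (best_mm < 0) {  // contig shorter than path: truncated comparison
        int mt = (int)std::min<long>(m, len0);
        int mm = 0;
        for (int i = 0; i < mt; ++i)
          if (S[len0 - mt + i] != P[i]) ++mm;
        best_mm = mm + (m - mt);
      }
    }
    std::vector<int> rid, roff;
    std::vector<std::string> rseq;
    for (const auto& a : st.pr) {
      if (a.matched < 0) continue;
      std::string os = idx->reads[a.read];
      if (a.strand == 1) os = revcomp(os);
      rid.push_back(a.read / 2 + 1);
      roff.push_back((int)(a.off - len0));
      rseq.push_back(os);
    }
    return List::create(
        _["seq"] = P, _["first_base"] = std::string(1, st.first),
        _["reads"] = DataFrame::create(_["read_id"] = rid, _["off"] = roff,
                                       _["seq"] = rseq,
                                       _["stringsAsFactors"] = false),
        _["mismatches_vs_contig"] = best_mm,
        _["died_early"] = (int)P.size() < horizon,
        _["pair_distances"] = NumericVector(st.pair_d.begin(),
                                            st.pair_d.end()));
  }

  List extract_paths_at_branch(const int cnt[4]) {
    int horizon;
    if (is_n >= cfg.min_insert_n)
      horizon = (int)(ins_mean() + cfg.insert_sd_mult * ins_sd());
    else
      horizon = 3 * rl;
    horizon = std::min(horizon, 2000);
    const int max_states = 8;
    long len0 = (long)S.size();
    std::vector<PathState> work, out;
    for (int c = 0; c < 4; ++c) {
      if (cnt[c] == 0) continue;
      char b = code_base(c);
      PathState st;
      st.first = st.next = b;
      for (const ARec& a : act) {
        int L = rlen(a.read);
        int q = (int)(len0 - a.off);
        if (q >= L) continue;
        if (obase(a.read, a.strand, q) != b) continue;
        PathRead prd{a.read, a.off, a.strand, a.matched, a.mm, a.mm_run,
                     -1, false};
        prd.pspan = path_read_span(prd);
        if (prd.pspan > 0) st.pair_d.push_back(prd.pspan);
        st.pr.push_back(prd);
        st.pkey.insert(rec_key(a.read, a.off));
      }
      work.push_back(std::move(st));
    }
    while (!work.empty()) {
      PathState st = std::move(work.back());
      work.pop_back();
      run_path_state(std::move(st), horizon, work, out, max_states);
    }
    List paths;
    for (const auto& st : out) paths.push_back(finish_path(st, horizon));
    return paths;
  }

  // ------------------------------------------------------------------
  // One extension decision.  Returns true if a base was appended.
  // ------------------------------------------------------------------
  bool extend_once() {
    recruit_terminal();
    int cnt[4];
    bool decided = false;
    char base = 'N';
    // --- paired-end pool first ---
    if (paired_usable()) {
      tally_paired(cnt);
      int mx = 0, mxc = 0, sec = 0;
      for (int c = 0; c < 4; ++c) {
        if (cnt[c] >= mx) { sec = mx; mx = cnt[c]; mxc = c; }
        else if (cnt[c] > sec) sec = cnt[c];
      }
      if (mx >= cfg.min_pairs_paired) {
        if (mx > sec && sec < cfg.min_branch_support) {
          // no competing base with real support: plain majority extension
          append_base(code_base(mxc));
          return true;
        }
        // paired branch
        double f[4];
        features_from(cnt, f);
        double dv;
        int v = navigate(f, true, dv);
        if (v == 1) {
          base = code_base(mxc);
          trace_row("paired", NA_INTEGER, f,
                    cfg.nav_mode == 0 ? "majority"
                                      : (cfg.nav_mode == 2 && svm_paired.has
                                             ? "svm" : "heuristic"),
                    "extend", std::string(1, base), dv);
          append_base(base);
          return true;
        } else if (v == 0) {
          trace_row("paired", NA_INTEGER, f,
                    cfg.nav_mode == 0 ? "majority"
                                      : (cfg.nav_mode == 2 && svm_paired.has
                                             ? "svm" : "heuristic"),
                    "stop", "", dv);
          return false;
        } else {
          // low confidence -> look-ahead (or stop if disabled)
          return lookahead_branch(cnt, "paired", NA_INTEGER, f, dv);
        }
      }
      // fewer than min_pairs_paired supporting pairs: fall through
      (void)decided;
    }
    // --- single-end sweep O_max .. O_min ---
    for (int O = cfg.Omax; O >= cfg.Omin; --O) {
      tally_single(O, cnt);
      int tot = cnt[0] + cnt[1] + cnt[2] + cnt[3];
      if (tot == 0) continue;
      int mx = 0, mxc = 0, sec = 0;
      for (int c = 0; c < 4; ++c) {
        if (cnt[c] >= mx) { sec = mx; mx = cnt[c]; mxc = c; }
        else if (cnt[c] > sec) sec = cnt[c];
      }
      if (sec < cfg.min_branch_support) {
        if (mx > sec) {
          append_base(code_base(mxc));
          return true;
        }
        return false;  // tie without real support: stop conservatively
      }
      double f[4];
      features_from(cnt, f);
      double dv;
      int v = navigate(f, false, dv);
      std::string stage = cfg.nav_mode == 0
                              ? "majority"
                              : (cfg.nav_mode == 2 && svm_single.has
                                     ? "svm" : "heuristic");
      if (v == 1) {
        base = code_base(mxc);
        trace_row("single", O, f, stage, "extend", std::string(1, base), dv);
        append_base(base);
        return true;
      } else if (v == 0) {
        trace_row("single", O, f, stage, "stop", "", dv);
        return false;
      }
      return lookahead_branch(cnt, "single", O, f, dv);
    }
    return false;  // no supporting read at any O: gap, stop
  }

  bool lookahead_branch(const int cnt[4], const std::string& mode, int O,
                        const double* f, double dv) {
    if (!use_lookahead || la_cb == nullptr) {
      trace_row(mode, O, f,
                cfg.nav_mode == 2 ? "svm" : "heuristic", "stop", "", dv);
      return false;
    }
    List paths = extract_paths_at_branch(cnt);
    List ins = List::create(_["mean"] = ins_mean(), _["sd"] = ins_sd(),
                            _["n"] = is_n, _["read_len"] = rl);
    List res = (*la_cb)(paths, ins);
    std::string action = as<std::string>(res["action"]);
    std::string stage = "lookahead_";
    stage += as<std::string>(res["stage"]);
    if (action == "extend") {
      std::string b = as<std::string>(res["base"]);
      trace_row(mode, O, f, stage, "extend", b, dv);
      if (stage == "lookahead_repeat") {
        // merged tandem paths: the trailing path's reads are mis-phased
        // here; release them so the index re-recruits them at their
        // correct copy further along the contig
        long len = (long)S.size();
        std::vector<ARec> keep;
        for (const ARec& a : act) {
          int q = (int)(len - a.off);
          if (q < rlen(a.read) && obase(a.read, a.strand, q) != b[0]) {
            active_key.erase(rec_key(a.read, a.off));
            rejected.insert(rec_key(a.read, a.off));
          } else
            keep.push_back(a);
        }
        act.swap(keep);
      }
      append_base(b[0]);
      return true;
    }
    trace_row(mode, O, f, stage, "stop", "", dv);
    return false;
  }

  void extend_run() {
    while ((int)S.size() < cfg.max_contig_len) {
      if (!extend_once()) break;
    }
  }

  // reverse-complement the contig and all records (5' extension reuses the
  // 3' machinery)
  void flip() {
    long len = (long)S.size();
    S = revcomp(S);
    std::reverse(support.begin(), support.end());
    for (auto& fr : fullv) {
      fr.off = (int32_t)(len - fr.off - rlen(fr.read));
      fr.strand ^= 1;
    }
    last_full_end = 0;
    for (auto& fr : fullv)
      last_full_end =
          std::max(last_full_end, (long)fr.off + rlen(fr.read));
    act.clear();
    active_key.clear();
    rejected.clear();
    recruit_window(len - rl - cfg.k);
    cur_pass = 2;
  }

  // assemble one contig from a seed k-mer; returns final sequence
  std::string run_contig(const std::string& seed) {
    reset_contig(seed);
    cur_pass = 1;
    extend_run();
    flip();
    extend_run();
    flip();  // restore original orientation
    cur_pass = 1;
    return S;
  }

  DataFrame trace_df() const {
    return DataFrame::create(
        _["contig"] = tr_contig, _["at"] = tr_at, _["pass"] = tr_pass,
        _["mode"] = tr_mode, _["O"] = tr_O, _["maxOcc"] = tr_maxOcc,
        _["secOcc"] = tr_secOcc, _["covRatio"] = tr_covRatio,
        _["gapLen"] = tr_gapLen, _["stage"] = tr_stage,
        _["action"] = tr_action, _["base"] = tr_base,
        _["decision_value"] = tr_decval, _["context"] = tr_context,
        _["stringsAsFactors"] = false);
  }

  DataFrame records_df() const {
    std::vector<int> rid, mate, off;
    std::vector<std::string> strand;
    for (const auto& fr : fullv) {
      rid.push_back(fr.read / 2 + 1);
      mate.push_back(fr.read % 2 + 1);
      off.push_back(fr.off);
      strand.push_back(fr.strand == 0 ? "+" : "-");
    }
    return DataFrame::create(_["read_id"] = rid, _["mate"] = mate,
                             _["off"] = off, _["strand"] = strand,
                             _["stringsAsFactors"] = false);
  }
};

static void engine_setup_model(Engine& eng, List model) {
  double margin = 0.5;
  if (model.containsElementNamed("margin"))
    margin = as<double>(model["margin"]);
  eng.svm_paired = SvmM::parse(
      model.containsElementNamed("paired") ? (SEXP)model["paired"]
                                           : R_NilValue,
      margin);
  eng.svm_single = SvmM::parse(
      model.containsElementNamed("single") ? (SEXP)model["single"]
                                           : R_NilValue,
      margin);
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// Full phase-1 assembly over all reads in the index.
// [[Rcpp::export]]
List eng_assemble(SEXP idxp, List cfg_, List model, Function lookahead_cb,
                  bool use_lookahead, List insert_prior,
                  bool return_records) {
  XPtr<KmerIndex> idx(idxp);
  Cfg cfg = Cfg::parse(cfg_);
  Engine eng(idx, cfg);
  engine_setup_model(eng, model);
  eng.la_cb = &lookahead_cb;
  eng.use_lookahead = use_lookahead;
  if (insert_prior.size() > 0 && !Rf_isNull(insert_prior["n"]))
    eng.set_insert_prior(as<double>(insert_prior["mean"]),
                         as<double>(insert_prior["sd"]),
                         as<int>(insert_prior["n"]));
  std::vector<std::string> contigs;
  List recs;
  for (int r = 0; r < idx->n_reads(); ++r) {
    if (eng.used[r] || eng.tried_seed[r]) continue;
    eng.tried_seed[r] = 1;
    const std::string& s = idx->reads[r];
    if ((int)s.size() < cfg.k) continue;
    uint64_t code;
    if (!encode_kmer(s, 0, cfg.k, code)) continue;
    uint64_t rc = revcomp_code(code, cfg.k);
    if (idx->freq(code <= rc ? code : rc) <= cfg.low_freq_threshold)
      continue;  // low-frequency (likely erroneous) start k-mers excluded
    eng.cur_contig = (int)contigs.size() + 1;
    std::string ctg = eng.run_contig(s.substr(0, cfg.k));
    if ((int)ctg.size() >= cfg.min_contig_len) {
      contigs.push_back(ctg);
      if (return_records) recs.push_back(eng.records_df());
    } else {
      eng.cur_contig = -eng.cur_contig;  // discarded; trace rows keep the id
    }
    Rcpp::checkUserInterrupt();
  }
  int n_used = 0;
  for (auto u : eng.used) n_used += u;
  return List::create(
      _["contigs"] = contigs, _["trace"] = eng.trace_df(),
      _["insert"] = List::create(_["mean"] = eng.ins_mean(),
                                 _["sd"] = eng.ins_sd(), _["n"] = eng.is_n),
      _["n_reads_used"] = n_used,
      _["records"] = recs);
}

// Build the alignment state for an arbitrary contig (no global read
// consumption): pools, support, insert estimate.
// [[Rcpp::export]]
List eng_probe(SEXP idxp, std::string contig, List cfg_, List insert_prior) {
  XPtr<KmerIndex> idx(idxp);
  Cfg cfg = Cfg::parse(cfg_);
  Engine eng(idx, cfg);
  if (insert_prior.size() > 0 && !Rf_isNull(insert_prior["n"]))
    eng.set_insert_prior(as<double>(insert_prior["mean"]),
                         as<double>(insert_prior["sd"]),
                         as<int>(insert_prior["n"]));
  eng.reset_contig(contig);
  eng.recruit_window(0);
  long len = (long)contig.size();
  // pool 1: partials at the 3' end
  std::vector<int> p1_read, p1_mate, p1_off, p1_ov;
  std::vector<std::string> p1_strand, p1_next;
  std::vector<bool> p1_paired;
  double mu = eng.ins_mean(), sd = eng.ins_sd();
  for (const ARec& a : eng.act) {
    int L = eng.rlen(a.read);
    int q = (int)(len - a.off);
    if (q >= L) continue;
    p1_read.push_back(a.read / 2 + 1);
    p1_mate.push_back(a.read % 2 + 1);
    p1_off.push_back(a.off);
    p1_strand.push_back(a.strand == 0 ? "+" : "-");
    p1_ov.push_back(q);
    p1_next.push_back(std::string(1, eng.obase(a.read, a.strand, q)));
    bool paired = false;
    if (a.strand == 1) {
      auto it = eng.full_by_read.find(idx->mate_of(a.read));
      if (it != eng.full_by_read.end()) {
        const FRec& mf = eng.fullv[it->second];
        if (mf.strand == 0 && mf.off <= a.off) {
          double span = (double)a.off + L - mf.off;
          paired = eng.is_n >= cfg.min_insert_n
                       ? std::fabs(span - mu) <= cfg.insert_sd_mult * sd
                       : true;
        }
      }
    }
    p1_paired.push_back(paired);
  }
  return List::create(
      _["pool1"] = DataFrame::create(
          _["read_id"] = p1_read, _["mate"] = p1_mate, _["off"] = p1_off,
          _["strand"] = p1_strand, _["overlap"] = p1_ov,
          _["next_base"] = p1_next, _["paired_support"] = p1_paired,
          _["stringsAsFactors"] = false),
      _["pool2"] = eng.records_df(),
      _["support"] = IntegerVector(eng.support.begin(), eng.support.end()),
      _["insert"] = List::create(_["mean"] = eng.ins_mean(),
                                 _["sd"] = eng.ins_sd(), _["n"] = eng.is_n));
}

// One extension decision on an arbitrary contig (look-ahead reported, not
// invoked).
// [[Rcpp::export]]
List eng_step(SEXP idxp, std::string contig, List cfg_, List model,
              List insert_prior) {
  XPtr<KmerIndex> idx(idxp);
  Cfg cfg = Cfg::parse(cfg_);
  Engine eng(idx, cfg);
  engine_setup_model(eng, model);
  eng.use_lookahead = false;
  if (insert_prior.size() > 0 && !Rf_isNull(insert_prior["n"]))
    eng.set_insert_prior(as<double>(insert_prior["mean"]),
                         as<double>(insert_prior["sd"]),
                         as<int>(insert_prior["n"]));
  eng.reset_contig(contig);
  eng.recruit_window(0);
  // replicate extend_once() but report instead of acting
  int cnt[4];
  if (eng.paired_usable()) {
    eng.tally_paired(cnt);
    int mx = 0, mxc = 0, sec = 0;
    for (int c = 0; c < 4; ++c) {
      if (cnt[c] >= mx) { sec = mx; mx = cnt[c]; mxc = c; }
      else if (cnt[c] > sec) sec = cnt[c];
    }
    if (mx >= cfg.min_pairs_paired) {
      if (mx > sec && sec < cfg.min_branch_support)
        return List::create(_["action"] = "extend",
                            _["base"] = std::string(1, code_base(mxc)),
                            _["mode"] = "paired", _["branch"] = false);
      double f[4];
      eng.features_from(cnt, f);
      double dv;
      int v = eng.navigate(f, true, dv);
      std::string act = v == 1 ? "extend" : (v == 0 ? "stop"
                                                    : "low_confidence");
      return List::create(
          _["action"] = act,
          _["base"] = std::string(1, code_base(mxc)), _["mode"] = "paired",
          _["branch"] = true,
          _["features"] = NumericVector::create(f[0], f[1], f[2], f[3]),
          _["decision_value"] = dv,
          _["tally"] = IntegerVector::create(_["A"] = cnt[0], _["C"] = cnt[1],
                                             _["G"] = cnt[2],
                                             _["T"] = cnt[3]));
    }
  }
  for (int O = cfg.Omax; O >= cfg.Omin; --O) {
    eng.tally_single(O, cnt);
    int tot = cnt[0] + cnt[1] + cnt[2] + cnt[3];
    if (tot == 0) continue;
    int mx = 0, mxc = 0, sec = 0;
    for (int c = 0; c < 4; ++c) {
      if (cnt[c] >= mx) { sec = mx; mx = cnt[c]; mxc = c; }
      else if (cnt[c] > sec) sec = cnt[c];
    }
    if (sec < cfg.min_branch_support) {
      if (mx > sec)
        return List::create(_["action"] = "extend",
                            _["base"] = std::string(1, code_base(mxc)),
                            _["mode"] = "single", _["O"] = O,
                            _["branch"] = false);
      return List::create(_["action"] = "stop", _["mode"] = "single",
                          _["O"] = O, _["branch"] = false);
    }
    double f[4];
    eng.features_from(cnt, f);
    double dv;
    int v = eng.navigate(f, false, dv);
    std::string act = v == 1 ? "extend" : (v == 0 ? "stop"
                                                  : "low_confidence");
    return List::create(
        _["action"] = act, _["base"] = std::string(1, code_base(mxc)),
        _["mode"] = "single", _["O"] = O, _["branch"] = true,
        _["features"] = NumericVector::create(f[0], f[1], f[2], f[3]),
        _["decision_value"] = dv,
        _["tally"] = IntegerVector::create(_["A"] = cnt[0], _["C"] = cnt[1],
                                           _["G"] = cnt[2], _["T"] = cnt[3]));
  }
  return List::create(_["action"] = "stop", _["mode"] = "gap",
                      _["branch"] = false);
}

// Candidate forward paths at the current branch of an arbitrary contig.
// [[Rcpp::export]]
List eng_paths(SEXP idxp, std::string contig, List cfg_, List insert_prior) {
  XPtr<KmerIndex> idx(idxp);
  Cfg cfg = Cfg::parse(cfg_);
  Engine eng(idx, cfg);
  if (insert_prior.size() > 0 && !Rf_isNull(insert_prior["n"]))
    eng.set_insert_prior(as<double>(insert_prior["mean"]),
                         as<double>(insert_prior["sd"]),
                         as<int>(insert_prior["n"]));
  eng.reset_contig(contig);
  eng.recruit_window(0);
  int cnt[4];
  // tally at the first O with support (same rule as extension)
  if (eng.paired_usable()) {
    eng.tally_paired(cnt);
    int mx = 0;
    for (int c = 0; c < 4; ++c) mx = std::max(mx, cnt[c]);
    if (mx >= cfg.min_pairs_paired) return eng.extract_paths_at_branch(cnt);
  }
  for (int O = cfg.Omax; O >= cfg.Omin; --O) {
    eng.tally_single(O, cnt);
    if (cnt[0] + cnt[1] + cnt[2] + cnt[3] > 0)
      return eng.extract_paths_at_branch(cnt);
  }
  return List();
}

// Extend a given contig at its 3' end only (local assembly for gap filling).
// [[Rcpp::export]]
List eng_extend_from(SEXP idxp, std::string contig, List cfg_, List model,
                     Function lookahead_cb, bool use_lookahead,
                     List insert_prior, int max_bases) {
  XPtr<KmerIndex> idx(idxp);
  Cfg cfg = Cfg::parse(cfg_);
  Engine eng(idx, cfg);
  engine_setup_model(eng, model);
  eng.la_cb = &lookahead_cb;
  eng.use_lookahead = use_lookahead;
  if (insert_prior.size() > 0 && !Rf_isNull(insert_prior["n"]))
    eng.set_insert_prior(as<double>(insert_prior["mean"]),
                         as<double>(insert_prior["sd"]),
                         as<int>(insert_prior["n"]));
  eng.reset_contig(contig);
  eng.recruit_window(0);
  long len0 = (long)contig.size();
  eng.cfg.max_contig_len = (int)std::min<long>(
      (long)cfg.max_contig_len, len0 + (long)max_bases);
  eng.extend_run();
  return List::create(_["seq"] = eng.S,
                      _["added"] = (int)((long)eng.S.size() - len0));
}

// All full-length alignments of indexed reads onto a contig (phase 2).
// [[Rcpp::export]]
DataFrame aln_full(SEXP idxp, std::string contig, List cfg_) {
  XPtr<KmerIndex> idx(idxp);
  Cfg cfg = Cfg::parse(cfg_);
  long len = (long)contig.size();
  std::vector<int> rid, mate, off;
  std::vector<std::string> strand;
  std::vector<int> mmv;
  std::unordered_set<int64_t> seen;
  for (long p = 0; p + cfg.k <= len; ++p) {
    uint64_t code;
    if (!encode_kmer(contig, p, cfg.k, code)) continue;
    uint64_t rc = revcomp_code(code, cfg.k);
    uint64_t ckey = code <= rc ? code : rc;
    uint8_t q_strand = code <= rc ? 0 : 1;
    auto it = idx->table.find(ckey);
    if (it == idx->table.end()) continue;
    for (const Occ& o : it->second) {
      uint8_t st = (o.strand == q_strand) ? 0 : 1;
      int L = (int)idx->reads[o.read].size();
      int pos_o = st == 0 ? o.pos : L - cfg.k - o.pos;
      long aoff = p - pos_o;
      if (aoff < 0 || aoff + L > len) continue;
      int64_t key = rec_key(o.read, (int32_t)aoff);
      if (seen.count(key)) continue;
      seen.insert(key);
      // verify full span
      const std::string& s = idx->reads[o.read];
      int matched = 0, mm = 0, run = 0, maxrun = 0;
      for (int i = 0; i < L; ++i) {
        char rb = st == 0 ? s[i] : comp_base(s[L - 1 - i]);
        if (rb == contig[aoff + i]) { ++matched; run = 0; }
        else { ++mm; if (++run > maxrun) maxrun = run; }
      }
      double sim = (double)matched / L;
      if (sim >= cfg.min_similarity - 1e-9 && maxrun <= cfg.Omin) {
        rid.push_back(o.read / 2 + 1);
        mate.push_back(o.read % 2 + 1);
        off.push_back((int)aoff);
        strand.push_back(st == 0 ? "+" : "-");
        mmv.push_back(mm);
      }
    }
  }
  return DataFrame::create(_["read_id"] = rid, _["mate"] = mate,
                           _["off"] = off, _["strand"] = strand,
                           _["mm"] = mmv, _["stringsAsFactors"] = false);
}
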