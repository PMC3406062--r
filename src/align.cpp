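// Affine-gap global alignment core (Gotoh three-state DP) with optionally
// free end gaps, plus the bulk operations built on it: identity scans,
// greedy abundance-ordered clustering, per-position match profiles and
// seed-anchored majority consensus.
//
// Conventions, shared with the R wrappers:
//   * a gap of length g costs gap_open + (g-1)*gap_extend (gap_open is the
//     cost of the first gapped base);
//   * with end_free, terminal gaps on either sequence score 0;
//   * traceback ties prefer diagonal (match/mismatch), then gap-in-b
//     (consuming a), then gap-in-a;
//   * identity = identical columns / max(columns outside the terminal-gap
//     spans, length of the shorter sequence); internal gaps count as
//     mismatched columns, and the max() keeps a degenerate short overlap of
//     two mostly-unrelated sequences from scoring as a high-identity match.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG = -1e18;

struct AlnResult {
  std::string a, b;  // gapped strings
  double score;
};

struct Params {
  double mat, mis, go, ge;
  bool end_free;
};

// Full DP with traceback. Matrices are kept in function-static buffers to
// avoid reallocating on every call (single-threaded use only).
static AlnResult gotoh_align(const std::string& A, const std::string& B,
                             const Params& p) {
  const int m = (int)A.size(), n = (int)B.size();
  static std::vector<double> H, E, F;
  const size_t need = (size_t)(m + 1) * (n + 1);
  if (H.size() < need) { H.resize(need); E.resize(need); F.resize(need); }
  const int W = n + 1;
#define IDX(i, j) ((size_t)(i) * W + (j))

  H[IDX(0, 0)] = 0.0;
  E[IDX(0, 0)] = F[IDX(0, 0)] = NEG;
  for (int j = 1; j <= n; ++j) {
    if (p.end_free) {
      H[IDX(0, j)] = 0.0;
      E[IDX(0, j)] = NEG;
    } else {
      double g = p.go + (j - 1) * p.ge;
      H[IDX(0, j)] = g;
      E[IDX(0, j)] = g;
    }
    F[IDX(0, j)] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    if (p.end_free) {
      H[IDX(i, 0)] = 0.0;
      F[IDX(i, 0)] = NEG;
    } else {
      double g = p.go + (i - 1) * p.ge;
      H[IDX(i, 0)] = g;
      F[IDX(i, 0)] = g;
    }
    E[IDX(i, 0)] = NEG;
  }

  for (int i = 1; i <= m; ++i) {
    const char ai = A[i - 1];
    for (int j = 1; j <= n; ++j) {
      double e = std::max(H[IDX(i, j - 1)] + p.go, E[IDX(i, j - 1)] + p.ge);
      double f = std::max(H[IDX(i - 1, j)] + p.go, F[IDX(i - 1, j)] + p.ge);
      double s = (ai == B[j - 1]) ? p.mat : p.mis;
      double d = H[IDX(i - 1, j - 1)] + s;
      E[IDX(i, j)] = e;
      F[IDX(i, j)] = f;
      H[IDX(i, j)] = std::max(d, std::max(e, f));
    }
  }

  // termination: with free end gaps, best cell on the last row/column,
  // preferring the least trimming (then last-column over last-row).
  int si = m, sj = n;
  double best = H[IDX(m, n)];
  if (p.end_free) {
    for (int i = m - 1; i >= 0; --i)
      if (H[IDX(i, n)] > best) { best = H[IDX(i, n)]; si = i; sj = n; }
    for (int j = n - 1; j >= 0; --j)
      if (H[IDX(m, j)] > best) { best = H[IDX(m, j)]; si = m; sj = j; }
  }

  std::string ra, rb;  // built reversed
  ra.reserve(m + n);
  rb.reserve(m + n);
  // trailing free gaps
  for (int i = m; i > si; --i) { ra.push_back(A[i - 1]); rb.push_back('-'); }
  for (int j = n; j > sj; --j) { ra.push_back('-'); rb.push_back(B[j - 1]); }

  int i = si, j = sj;
  char state = 'H';
  while (i > 0 || j > 0) {
    if (i == 0) {  // only B left (leading region)
      --j;
      ra.push_back('-');
      rb.push_back(B[j]);
      continue;
    }
    if (j == 0) {
      ra.push_back(A[i - 1]);
      rb.push_back('-');
      --i;
      continue;
    }
    if (state == 'H') {
      double s = (A[i - 1] == B[j - 1]) ? p.mat : p.mis;
      double h = H[IDX(i, j)];
      if (h == H[IDX(i - 1, j - 1)] + s) {
        ra.push_back(A[i - 1]);
        rb.push_back(B[j - 1]);
        --i; --j;
      } else if (h == F[IDX(i, j)]) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') {  // gap in b, consume a
      ra.push_back(A[i - 1]);
      rb.push_back('-');
      double f = F[IDX(i, j)];
      --i;
      state = (f == H[IDX(i, j)] + p.go) ? 'H' : 'F';
    } else {  // 'E': gap in a, consume b
      ra.push_back('-');
      rb.push_back(B[j - 1]);
      double e = E[IDX(i, j)];
      --j;
      state = (e == H[IDX(i, j)] + p.go) ? 'H' : 'E';
    }
  }
#undef IDX
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  AlnResult r;
  r.a = ra;
  r.b = rb;
  r.score = best;
  return r;
}

struct AlnStats {
  double score;
  int matches, core_cols, core_a, core_b, lead, trail;
  double identity, frac_a, frac_b;
};

static AlnStats stats_from(const AlnResult& r, int la, int lb) {
  const int L = (int)r.a.size();
  int lead = 0;
  while (lead < L && (r.a[lead] == '-' || r.b[lead] == '-')) ++lead;
  int trail = 0;
  while (trail < L - lead &&
         (r.a[L - 1 - trail] == '-' || r.b[L - 1 - trail] == '-'))
    ++trail;
  int matches = 0, core_a = 0, core_b = 0;
  for (int i = lead; i < L - trail; ++i) {
    if (r.a[i] != '-') ++core_a;
    if (r.b[i] != '-') ++core_b;
    if (r.a[i] != '-' && r.a[i] == r.b[i]) ++matches;
  }
  AlnStats s;
  s.score = r.score;
  s.matches = matches;
  s.core_cols = L - lead - trail;
  s.core_a = core_a;
  s.core_b = core_b;
  s.lead = lead;
  s.trail = trail;
  // identity denominator: the aligned core, but never less than the shorter
  // sequence -- a degenerate overlap that leaves most of both sequences in
  // terminal gaps must not look like a high-identity match
  int denom = std::max(s.core_cols, std::min(la, lb));
  s.identity = denom > 0 ? (double)matches / denom : 0.0;
  s.frac_a = la > 0 ? std::min(1.0, (double)core_a / la) : 0.0;
  s.frac_b = lb > 0 ? std::min(1.0, (double)core_b / lb) : 0.0;
  return s;
}

// ---- k-mer prescreen -------------------------------------------------------
// Lossless-in-practice filter used only inside the clustering scans: if two
// sequences share fewer distinct 8-mers than is possible for any alignment
// with identity >= threshold (with a generous slack of 2% of the query
// length on the number of differences), the alignment is skipped.

static const int KMER = 8;

static bool kmer_set(const std::string& s, std::vector<uint32_t>& out) {
  const int n = (int)s.size();
  out.clear();
  if (n < KMER) return false;
  uint32_t v = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c;
    switch (s[i]) {
      case 'A': c = 0; break;
      case 'C': c = 1; break;
      case 'G': c = 2; break;
      case 'T': c = 3; break;
      default: return false;  // non-ACGT: no filtering
    }
    v = ((v << 2) | c) & 0xFFFF;
    if (++run >= KMER) out.push_back(v);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return true;
}

static int shared_count(const std::vector<uint32_t>& x,
                        const std::vector<uint32_t>& y) {
  int c = 0;
  size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (x[i] > y[j]) ++j;
    else { ++c; ++i; ++j; }
  }
  return c;
}

static bool filter_pass(const std::vector<uint32_t>& kq, int la, int lb,
                        const std::vector<uint32_t>& kr, double threshold) {
  if (kq.empty() || kr.empty()) return true;
  int ldiff = la > lb ? la - lb : lb - la;
  if (10 * ldiff > la) return true;  // lengths too different: no filtering
  int emax = (int)std::ceil((1.0 - threshold) * la) +
             (int)std::ceil(0.02 * la) + ldiff;
  int need = (la - KMER + 1) - KMER * emax;
  if (need <= 0) return true;
  return shared_count(kq, kr) >= need;
}

// ---- exported --------------------------------------------------------------

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, double match_score,
               double mismatch, double gap_open, double gap_extend,
               bool end_free) {
  Params p{match_score, mismatch, gap_open, gap_extend, end_free};
  AlnResult r = gotoh_align(a, b, p);
  return List::create(_["aligned_a"] = r.a, _["aligned_b"] = r.b,
                      _["score"] = r.score);
}

// [[Rcpp::export]]
NumericVector cpp_align_stats(std::string a, std::string b,
                              double match_score, double mismatch,
                              double gap_open, double gap_extend,
                              bool end_free) {
  Params p{match_score, mismatch, gap_open, gap_extend, end_free};
  AlnResult r = gotoh_align(a, b, p);
  AlnStats s = stats_from(r, (int)a.size(), (int)b.size());
  NumericVector out = NumericVector::create(
      _["score"] = s.score, _["identity"] = s.identity,
      _["matches"] = (double)s.matches, _["core_columns"] = (double)s.core_cols,
      _["aligning_fraction_a"] = s.frac_a, _["aligning_fraction_b"] = s.frac_b);
  return out;
}

// 0/1 per position of `a`: 1 if that base is aligned to an identical base.
// [[Rcpp::export]]
IntegerVector cpp_match_profile(std::string a, std::string b,
                                double match_score, double mismatch,
                                double gap_open, double gap_extend,
                                bool end_free) {
  Params p{match_score, mismatch, gap_open, gap_extend, end_free};
  AlnResult r = gotoh_align(a, b, p);
  IntegerVector prof((int)a.size());
  int pos = 0;
  for (size_t i = 0; i < r.a.size(); ++i) {
    if (r.a[i] != '-') {
      prof[pos] = (r.b[i] != '-' && r.a[i] == r.b[i]) ? 1 : 0;
      ++pos;
    }
  }
  return prof;
}

// fraction of query positions aligned to an identical base, per ref.
// [[Rcpp::export]]
NumericVector cpp_profile_identity_many(std::string query,
                                        CharacterVector refs,
                                        double match_score, double mismatch,
                                        double gap_open, double gap_extend,
                                        bool end_free) {
  Params p{match_score, mismatch, gap_open, gap_extend, end_free};
  const int n = refs.size();
  const int L = (int)query.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    AlnResult r = gotoh_align(query, as<std::string>(refs[i]), p);
    int matched = 0;
    for (size_t c = 0; c < r.a.size(); ++c)
      if (r.a[c] != '-' && r.a[c] == r.b[c]) ++matched;
    out[i] = L > 0 ? (double)matched / L : 0.0;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// identity and aligning fraction (of the query) against every ref.
// [[Rcpp::export]]
NumericMatrix cpp_identity_many(std::string query, CharacterVector refs,
                                double match_score, double mismatch,
                                double gap_open, double gap_extend,
                                bool end_free) {
  Params p{match_score, mismatch, gap_open, gap_extend, end_free};
  const int n = refs.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("identity", "aligning_fraction",
                                          "score");
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(refs[i]);
    AlnResult a = gotoh_align(query, r, p);
    AlnStats s = stats_from(a, (int)query.size(), (int)r.size());
    out(i, 0) = s.identity;
    out(i, 1) = s.frac_a;
    out(i, 2) = s.score;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// first ref (in order) whose identity to the query reaches the threshold.
// [[Rcpp::export]]
List cpp_first_match(std::string query, CharacterVector refs, double threshold,
                     double match_score, double mismatch, double gap_open,
                     double gap_extend, bool end_free, bool use_filter) {
  Params p{match_score, mismatch, gap_open, gap_extend, end_free};
  std::vector<uint32_t> kq;
  bool fq = use_filter && kmer_set(query, kq);
  std::vector<uint32_t> kr;
  for (int i = 0; i < refs.size(); ++i) {
    std::string r = as<std::string>(refs[i]);
    if (fq) {
      std::vector<uint32_t> krv;
      if (kmer_set(r, krv) &&
          !filter_pass(kq, (int)query.size(), (int)r.size(), krv, threshold))
        continue;
    }
    AlnResult a = gotoh_align(query, r, p);
    AlnStats s = stats_from(a, (int)query.size(), (int)r.size());
    if (s.identity >= threshold - 1e-12)
      return List::create(_["index"] = i + 1, _["identity"] = s.identity);
  }
  return List::create(_["index"] = 0, _["identity"] = NA_REAL);
}

// Greedy abundance-ordered clustering pass: sequences (already sorted by
// abundance) join the first existing cluster whose representative they match
// at >= threshold, else found a new cluster. Representatives are the
// founders' own sequences. Returns 1-based cluster index per sequence.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 double match_score, double mismatch,
                                 double gap_open, double gap_extend,
                                 bool end_free, bool use_filter) {
  Params p{match_score, mismatch, gap_open, gap_extend, end_free};
  const int n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> reps;
  std::vector<std::vector<uint32_t>> repk;
  std::vector<bool> repf;
  std::vector<uint32_t> kq;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    bool fq = use_filter && kmer_set(s, kq);
    int hit = 0;
    for (size_t c = 0; c < reps.size(); ++c) {
      if (fq && repf[c] &&
          !filter_pass(kq, (int)s.size(), (int)reps[c].size(), repk[c],
                       threshold))
        continue;
      AlnResult a = gotoh_align(s, reps[c], p);
      AlnStats st = stats_from(a, (int)s.size(), (int)reps[c].size());
      if (st.identity >= threshold - 1e-12) { hit = (int)c + 1; break; }
    }
    if (hit == 0) {
      reps.push_back(s);
      std::vector<uint32_t> kv;
      bool ok = use_filter && kmer_set(s, kv);
      repk.push_back(kv);
      repf.push_back(ok);
      hit = (int)reps.size();
    }
    assign[i] = hit;
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return assign;
}

// Seed-anchored weighted majority consensus. Members are aligned to the
// seed; per seed column the weighted-majority base wins (ties toward the
// seed base, columns with a strict gap majority are deleted); insertion
// columns relative to the seed are emitted only when a strict majority of
// the total weight carries a base there.
// [[Rcpp::export]]
std::string cpp_consensus(std::string seed, CharacterVector members,
                          NumericVector weights, double match_score,
                          double mismatch, double gap_open, double gap_extend,
                          bool end_free) {
  Params p{match_score, mismatch, gap_open, gap_extend, end_free};
  const int L = (int)seed.size();
  if (members.size() != weights.size()) stop("members/weights length mismatch");
  // counts[5][L]: A C G T gap
  std::vector<double> counts(5 * (size_t)L, 0.0);
  std::map<std::pair<int, int>, std::array<double, 4>> ins;
  double W = 0.0;
  auto base_idx = [](char c) {
    switch (c) {
      case 'A': return 0;
      case 'C': return 1;
      case 'G': return 2;
      case 'T': return 3;
      default: return -1;
    }
  };
  for (int mi = 0; mi < members.size(); ++mi) {
    std::string mem = as<std::string>(members[mi]);
    double w = weights[mi];
    W += w;
    AlnResult r = gotoh_align(mem, seed, p);
    int sp = 0;   // seed positions consumed (0..L)
    int off = 0;  // insertion offset since last seed position
    for (size_t c = 0; c < r.a.size(); ++c) {
      if (r.b[c] != '-') {
        // seed column sp (0-based)
        int bi = (r.a[c] == '-') ? 4 : base_idx(r.a[c]);
        if (bi < 0) bi = 4;  // unknown base: treat as gap vote
        counts[(size_t)bi * L + sp] += w;
        ++sp;
        off = 0;
      } else if (r.a[c] != '-') {
        int bi = base_idx(r.a[c]);
        if (bi >= 0) {
          auto key = std::make_pair(sp, off);
          auto it = ins.find(key);
          if (it == ins.end())
            it = ins.emplace(key, std::array<double, 4>{0, 0, 0, 0}).first;
          it->second[bi] += w;
        }
        ++off;
      }
    }
    if (mi % 32 == 0) Rcpp::checkUserInterrupt();
  }
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  out.reserve(L + 8);
  auto emit_ins = [&](int pos) {
    for (int off = 0;; ++off) {
      auto it = ins.find(std::make_pair(pos, off));
      if (it == ins.end()) break;
      int bi = 0;
      for (int k = 1; k < 4; ++k)
        if (it->second[k] > it->second[bi]) bi = k;
      if (it->second[bi] > W / 2.0) out.push_back(BASES[bi]);
    }
  };
  emit_ins(0);
  for (int pcol = 0; pcol < L; ++pcol) {
    double gv = counts[4 * (size_t)L + pcol];
    int sb = base_idx(seed[pcol]);
    double maxv = gv;
    for (int k = 0; k < 4; ++k) maxv = std::max(maxv, counts[(size_t)k * L + pcol]);
    if (sb >= 0 && counts[(size_t)sb * L + pcol] == maxv) {
      out.push_back(seed[pcol]);  // ties go to the seed base
    } else if (gv == maxv) {
      bool base_ties = false;
      int bi = -1;
      for (int k = 0; k < 4; ++k)
        if (counts[(size_t)k * L + pcol] == maxv) { base_ties = true; bi = k; break; }
      if (base_ties) out.push_back(BASES[bi]);  // base preferred over gap on tie
      // else: strict gap majority -> column deleted
    } else {
      for (int k = 0; k < 4; ++k)
        if (counts[(size_t)k * L + pcol] == maxv) { out.push_back(BASES[k]); break; }
    }
    emit_ins(pcol + 1);
  }
  return out;
}
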