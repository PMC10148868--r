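#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// base encoding: A=0 C=1 G=2 T=3, anything else -1
static inline int enc(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// ---------------------------------------------------------------------------
// bisulfite read simulator
//
// Reads are drawn uniformly over [0, L - read_len]; each read is OT or OB
// with probability 1/2. On OT, top-strand Cs convert to T with probability
// conversion_rate unless the molecule is methylated at that site (Bernoulli
// with the site's methylation fraction); methylated Cs never convert. OB is
// the mirrored process on the bottom strand; the returned read is the
// bottom-strand sequence 5'->3'. Substitution errors are applied last.
// Uses R's RNG so set.seed() in the caller governs everything.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_reads(std::string genome, NumericVector fplus,
                        NumericVector fminus, int n_reads, int read_len,
                        double conversion_rate, double error_rate) {
  const int L = genome.size();
  if (read_len > L) stop("read_len exceeds genome length");
  CharacterVector reads(n_reads);
  IntegerVector pos(n_reads);
  IntegerVector frame(n_reads); // 0 = OT, 1 = OB
  const char *bases = "ACGT";
  std::string buf(read_len, 'N');
  for (int i = 0; i < n_reads; ++i) {
    int p = (int)std::floor(unif_rand() * (L - read_len + 1));
    if (p > L - read_len) p = L - read_len;
    int fr = unif_rand() < 0.5 ? 0 : 1;
    if (fr == 0) {
      for (int j = 0; j < read_len; ++j) {
        char g = genome[p + j];
        if (g == 'C') {
          double f = fplus[p + j];
          bool methylated = (f > 0.0) && (unif_rand() < f);
          if (!methylated && unif_rand() < conversion_rate) g = 'T';
        }
        buf[j] = g;
      }
    } else {
      // bottom strand 5'->3' runs right to left over the fragment
      for (int j = 0; j < read_len; ++j) {
        int t = p + read_len - 1 - j; // top-strand coordinate
        char b = comp(genome[t]);
        if (b == 'C') {
          double f = fminus[t];
          bool methylated = (f > 0.0) && (unif_rand() < f);
          if (!methylated && unif_rand() < conversion_rate) b = 'T';
        }
        buf[j] = b;
      }
    }
    if (error_rate > 0.0) {
      for (int j = 0; j < read_len; ++j) {
        if (unif_rand() < error_rate) {
          char cur = buf[j];
          char nb = cur;
          while (nb == cur) nb = bases[(int)std::floor(unif_rand() * 4.0) & 3];
          buf[j] = nb;
        }
      }
    }
    reads[i] = buf;
    pos[i] = p;
    frame[i] = fr;
  }
  return List::create(_["bases"] = reads, _["pos"] = pos, _["frame"] = frame);
}

// ---------------------------------------------------------------------------
// reduced-alphabet seeded bisulfite mapper
// ---------------------------------------------------------------------------
struct BsIndex {
  std::string genome;
  int k;
  std::unordered_map<uint64_t, std::vector<int>> ct; // C->T converted top
  std::unordered_map<uint64_t, std::vector<int>> ga; // G->A converted top
};

static void fill_kmers(const std::string &s, int k,
                       std::unordered_map<uint64_t, std::vector<int>> &m) {
  const int L = s.size();
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < L; ++i) {
    int e = enc(s[i]);
    if (e < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)e) & mask;
    if (++valid >= k) m[code].push_back(i - k + 1);
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string genome, int k) {
  if (k < 4 || k > 32) stop("seed length k must be in [4, 32]");
  if (k > (int)genome.size()) stop("seed length k exceeds genome length");
  BsIndex *idx = new BsIndex();
  idx->genome = genome;
  idx->k = k;
  std::string ct = genome, ga = genome;
  for (auto &c : ct) if (c == 'C') c = 'T';
  for (auto &c : ga) if (c == 'G') c = 'A';
  fill_kmers(ct, k, idx->ct);
  fill_kmers(ga, k, idx->ga);
  return XPtr<BsIndex>(idx, true);
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) { return XPtr<BsIndex>(xp)->k; }

// [[Rcpp::export]]
List cpp_index_query(SEXP xp, std::string kmer, std::string frame) {
  XPtr<BsIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal k");
  uint64_t code = 0;
  for (char c : kmer) {
    int e = enc(c);
    if (e < 0) return List::create(_["pos"] = IntegerVector(0));
    code = (code << 2) | (uint64_t)e;
  }
  auto &m = (frame == "OT") ? idx->ct : idx->ga;
  auto it = m.find(code);
  IntegerVector out;
  if (it != m.end()) out = wrap(it->second);
  return List::create(_["pos"] = out);
}

static inline bool encode_kmer(const std::string &s, int from, int k,
                               uint64_t &code) {
  code = 0;
  for (int i = from; i < from + k; ++i) {
    int e = enc(s[i]);
    if (e < 0) return false;
    code = (code << 2) | (uint64_t)e;
  }
  return true;
}

// bisulfite-aware mismatch count with early bail-out.
// frame 0 (OT): reference C with read T is free.
// frame 1 (OB, read given in top-strand orientation): reference G / read A free.
static int bs_mismatches(const std::string &g, int pos, const std::string &r,
                         int frame, int bail) {
  int mm = 0;
  const int n = r.size();
  for (int j = 0; j < n; ++j) {
    char gc = g[pos + j], rc = r[j];
    bool ok = (gc == rc) || (frame == 0 ? (gc == 'C' && rc == 'T')
                                        : (gc == 'G' && rc == 'A'));
    if (!ok && ++mm > bail) return mm;
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, int max_mismatch) {
  XPtr<BsIndex> idx(xp);
  const std::string &G = idx->genome;
  const int L = G.size(), k = idx->k;
  const int n = reads.size();
  IntegerVector out_pos(n), out_mm(n), out_status(n), out_frame(n);
  std::vector<std::pair<int,int>> cands; // (pos, frame)
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    const int len = r.size();
    out_pos[i] = NA_INTEGER; out_mm[i] = NA_INTEGER; out_frame[i] = NA_INTEGER;
    if (len < k) { out_status[i] = 2; continue; } // unmapped: too short
    cands.clear();
    std::string rc = revcomp(r);
    for (int fr = 0; fr < 2; ++fr) {
      std::string conv = (fr == 0) ? r : rc;
      for (auto &c : conv) {
        if (fr == 0) { if (c == 'C') c = 'T'; }
        else         { if (c == 'G') c = 'A'; }
      }
      auto &map = (fr == 0) ? idx->ct : idx->ga;
      int offs[2] = {0, len - k};
      for (int s = 0; s < (offs[0] == offs[1] ? 1 : 2); ++s) {
        uint64_t code;
        if (!encode_kmer(conv, offs[s], k, code)) continue;
        auto it = map.find(code);
        if (it == map.end()) continue;
        for (int hit : it->second) {
          int p = hit - offs[s];
          if (p >= 0 && p + len <= L) cands.push_back({p, fr});
        }
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    int best = max_mismatch + 1, nbest = 0, bpos = -1, bframe = -1;
    for (auto &cf : cands) {
      const std::string &q = (cf.second == 0) ? r : rc;
      int mm = bs_mismatches(G, cf.first, q, cf.second, best);
      if (mm < best) { best = mm; nbest = 1; bpos = cf.first; bframe = cf.second; }
      else if (mm == best && best <= max_mismatch) ++nbest;
    }
    if (best > max_mismatch)      out_status[i] = 2;       // unmapped
    else if (nbest > 1)           out_status[i] = 1;       // ambiguous
    else {
      out_status[i] = 0;                                   // unique
      out_pos[i] = bpos; out_mm[i] = best; out_frame[i] = bframe;
    }
  }
  return DataFrame::create(_["pos"] = out_pos, _["frame"] = out_frame,
                           _["mismatches"] = out_mm, _["status"] = out_status);
}

// ---------------------------------------------------------------------------
// per-cytosine pileup of uniquely mapped reads
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_pileup(std::string genome, IntegerVector pos, IntegerVector frame,
                CharacterVector reads) {
  const int L = genome.size();
  IntegerVector meth_p(L), tot_p(L), meth_m(L), tot_m(L);
  const int n = reads.size();
  for (int i = 0; i < n; ++i) {
    if (pos[i] == NA_INTEGER) continue;
    std::string r = as<std::string>(reads[i]);
    int p = pos[i], len = r.size();
    if (p < 0 || p + len > L) stop("alignment out of genome bounds");
    if (frame[i] == 0) { // OT interrogates top-strand Cs
      for (int j = 0; j < len; ++j) {
        if (genome[p + j] != 'C') continue;
        char b = r[j];
        if (b == 'C') { ++meth_p[p + j]; ++tot_p[p + j]; }
        else if (b == 'T') ++tot_p[p + j];
      }
    } else {             // OB interrogates bottom-strand Cs (top-strand Gs)
      std::string rc = revcomp(r);
      for (int j = 0; j < len; ++j) {
        if (genome[p + j] != 'G') continue;
        char b = rc[j]; // bottom base is the complement of this top-frame base
        if (b == 'G') { ++meth_m[p + j]; ++tot_m[p + j]; }
        else if (b == 'A') ++tot_m[p + j];
      }
    }
  }
  return List::create(_["meth_plus"] = meth_p, _["tot_plus"] = tot_p,
                      _["meth_minus"] = meth_m, _["tot_minus"] = tot_m);
}

// context of a cytosine: 0=CG 1=CHG 2=CHH 3=undefined
static inline int ctx_top(const std::string &g, int i) {
  const int L = g.size();
  if (i + 1 >= L) return 3;
  char b1 = g[i + 1];
  if (enc(b1) < 0) return 3;
  if (i + 2 >= L) return 3;
  char b2 = g[i + 2];
  if (enc(b2) < 0) return 3;
  if (b1 == 'G') return 0;
  return (b2 == 'G') ? 1 : 2;
}

static inline int ctx_bottom(const std::string &g, int i) {
  if (i - 1 < 0) return 3;
  char b1 = g[i - 1]; // complement is the next base on the bottom strand
  if (enc(b1) < 0) return 3;
  if (i - 2 < 0) return 3;
  char b2 = g[i - 2];
  if (enc(b2) < 0) return 3;
  if (b1 == 'C') return 0;          // comp == G
  return (b2 == 'C') ? 1 : 2;
}

// ---------------------------------------------------------------------------
// genome-wide anchored k-mer background counts, stratified by context
//
// For every cytosine position (both strands) whose k-window at the given
// anchor offset fits inside the genome, encode the window on the cytosine's
// own strand (5'->3') and tabulate per context class. Returns a 4^k x 4
// integer matrix (row = 2-bit word code, A=0 C=1 G=2 T=3, first base most
// significant; columns CG, CHG, CHH, undefined) with attribute "totals" =
// per-context window counts.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_anchored_kmer_counts(std::string genome, int k, int anchor) {
  if (anchor < 1 || anchor > k) stop("anchor must be in 1..k");
  const int L = genome.size();
  IntegerMatrix counts((int)std::pow(4.0, k), 4);
  NumericVector totals(4);
  // top strand: C at i, window [i-(anchor-1), i-(anchor-1)+k-1]
  for (int i = anchor - 1; i <= L - 1 - (k - anchor); ++i) {
    if (genome[i] != 'C') continue;
    uint64_t code;
    if (!encode_kmer(genome, i - (anchor - 1), k, code)) continue;
    int cx = ctx_top(genome, i);
    ++counts((int)code, cx);
    ++totals[cx];
  }
  // bottom strand: C under a top-strand G at i; window runs rightwards on the
  // bottom strand = top positions i+(anchor-1) .. i-(k-anchor), complemented
  for (int i = k - anchor; i <= L - 1 - (anchor - 1); ++i) {
    if (genome[i] != 'G') continue;
    uint64_t code = 0;
    bool ok = true;
    for (int t = i + (anchor - 1); t >= i - (k - anchor); --t) {
      int e = enc(comp(genome[t]));
      if (e < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)e;
    }
    if (!ok) continue;
    int cx = ctx_bottom(genome, i);
    ++counts((int)code, cx);
    ++totals[cx];
  }
  counts.attr("totals") = totals;
  return counts;
}
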