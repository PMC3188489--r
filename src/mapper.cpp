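// Seed-and-extend read mapper over a hashed k-mer genome index.
//
// Candidate enumeration is pigeonhole-complete: a read is probed with
// (max_mismatches + 1) non-overlapping seed chunks of the index k-mer
// length, so any alignment with at most max_mismatches Hamming mismatches
// must match one chunk exactly and is guaranteed to be found, provided
// (max_mismatches + 1) * k <= read length (validated on the R side).
// Candidates are restricted to the best (minimal) mismatch tier; ties up
// to the ambiguity cap are placed uniformly at random using R's RNG so
// that set.seed() governs reproducibility.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

struct KmerIndex {
  std::string genome;  // uppercase A/C/G/T (others break k-mer runs)
  int k;
  std::unordered_map<uint64_t, std::vector<int> > map;  // 0-based starts
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char base_comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = base_comp(s[i]);
  return out;
}

// [[Rcpp::export]]
SEXP kmer_index_build(std::string genome, int k) {
  if (k < 1) stop("k-mer length must be at least 1");
  if ((size_t)k > genome.size()) stop("k-mer length exceeds genome length");
  if (k > 31) stop("k-mer length must be at most 31");
  XPtr<KmerIndex> xp(new KmerIndex(), true);
  xp->genome = genome;
  xp->k = k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t key = 0;
  int valid = 0;
  for (size_t i = 0; i < genome.size(); ++i) {
    int c = base_code(genome[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= k) xp->map[key].push_back((int)(i) - k + 1);
  }
  return xp;
}

// [[Rcpp::export]]
IntegerVector kmer_index_lookup(SEXP xp_, std::string kmer) {
  XPtr<KmerIndex> xp(xp_);
  if ((int)kmer.size() != xp->k)
    stop("query length must equal the index k-mer length");
  uint64_t key = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int v = base_code(kmer[i]);
    if (v < 0) return IntegerVector(0);
    key = (key << 2) | (uint64_t)v;
  }
  std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
      xp->map.find(key);
  if (it == xp->map.end()) return IntegerVector(0);
  IntegerVector out(it->second.size());
  for (size_t i = 0; i < it->second.size(); ++i) out[i] = it->second[i] + 1;
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
int kmer_index_k(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return xp->k;
}

// [[Rcpp::export]]
int kmer_index_genome_length(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return (int)xp->genome.size();
}

struct Candidate {
  int pos;     // 0-based leftmost genome coordinate
  int strand;  // 0 = forward, 1 = reverse
  int mm;
};

static bool cand_less(const Candidate& a, const Candidate& b) {
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.strand < b.strand;
}

static void collect_candidates(const KmerIndex& idx, const std::string& s,
                               int strand, int max_mm,
                               std::vector<Candidate>& out) {
  const int len = (int)s.size();
  const int k = idx.k;
  const int L = (int)idx.genome.size();
  if (len < k || len > L) return;
  const int nseed = max_mm + 1;
  std::vector<int> offsets;
  for (int i = 0; i < nseed; ++i) {
    int o = i * k;
    if (o + k > len) o = len - k;  // clamp final chunk for short reads
    if (offsets.empty() || offsets.back() != o) offsets.push_back(o);
    if (o == len - k) break;
  }
  std::unordered_map<int, int> seen;  // genome start -> mismatch count
  for (size_t oi = 0; oi < offsets.size(); ++oi) {
    int o = offsets[oi];
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int v = base_code(s[o + j]);
      if (v < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)v;
    }
    if (!ok) continue;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        idx.map.find(key);
    if (it == idx.map.end()) continue;
    for (size_t pi = 0; pi < it->second.size(); ++pi) {
      int g = it->second[pi] - o;
      if (g < 0 || g + len > L) continue;
      if (seen.count(g)) continue;
      int d = 0;
      for (int j = 0; j < len; ++j) {
        if (idx.genome[g + j] != s[j] && ++d > max_mm) break;
      }
      seen[g] = d;
    }
  }
  for (std::unordered_map<int, int>::const_iterator it = seen.begin();
       it != seen.end(); ++it) {
    if (it->second <= max_mm) {
      Candidate c;
      c.pos = it->first;
      c.strand = strand;
      c.mm = it->second;
      out.push_back(c);
    }
  }
}

static void best_tier(std::vector<Candidate>& cands) {
  if (cands.empty()) return;
  int dmin = cands[0].mm;
  for (size_t i = 1; i < cands.size(); ++i)
    if (cands[i].mm < dmin) dmin = cands[i].mm;
  std::vector<Candidate> keep;
  for (size_t i = 0; i < cands.size(); ++i)
    if (cands[i].mm == dmin) keep.push_back(cands[i]);
  std::sort(keep.begin(), keep.end(), cand_less);
  cands.swap(keep);
}

// Candidate sites (best mismatch tier, both strands) for a single read.
// [[Rcpp::export]]
List map_candidates(SEXP xp_, std::string read, int max_mismatches) {
  XPtr<KmerIndex> xp(xp_);
  std::vector<Candidate> cands;
  collect_candidates(*xp, read, 0, max_mismatches, cands);
  collect_candidates(*xp, revcomp(read), 1, max_mismatches, cands);
  best_tier(cands);
  const int n = (int)cands.size();
  IntegerVector pos(n), strand(n), mm(n);
  for (int i = 0; i < n; ++i) {
    pos[i] = cands[i].pos + 1;
    strand[i] = cands[i].strand;
    mm[i] = cands[i].mm;
  }
  return List::create(_["pos"] = pos, _["strand"] = strand,
                      _["mismatches"] = mm);
}

// Vectorised mapping of a read set.  Status codes:
// 0 unmapped, 1 unique, 2 ambiguous_assigned, 3 discarded_too_ambiguous.
// [[Rcpp::export]]
List map_readset_cpp(SEXP xp_, CharacterVector reads, int max_mismatches,
                     int ambiguity_cap) {
  XPtr<KmerIndex> xp(xp_);
  const int n = reads.size();
  IntegerVector n_cand(n), pos(n), strand(n), mm(n), status(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    std::vector<Candidate> cands;
    collect_candidates(*xp, r, 0, max_mismatches, cands);
    collect_candidates(*xp, revcomp(r), 1, max_mismatches, cands);
    best_tier(cands);
    const int m = (int)cands.size();
    n_cand[i] = m;
    pos[i] = NA_INTEGER;
    strand[i] = NA_INTEGER;
    mm[i] = NA_INTEGER;
    if (m == 0) {
      status[i] = 0;
    } else if (m > ambiguity_cap) {
      status[i] = 3;
    } else {
      int chosen = 0;
      if (m > 1) {
        chosen = (int)(unif_rand() * m);
        if (chosen >= m) chosen = m - 1;
        status[i] = 2;
      } else {
        status[i] = 1;
      }
      pos[i] = cands[chosen].pos + 1;
      strand[i] = cands[chosen].strand;
      mm[i] = cands[chosen].mm;
    }
  }
  return List::create(_["n_candidates"] = n_cand, _["pos"] = pos,
                      _["strand"] = strand, _["mismatches"] = mm,
                      _["status"] = status);
}
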