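// Compiled kernels for the read mapper, pileup, and k-mer profiling.
// All coordinates are 0-based half-open; strand '-' means the read's
// reverse complement matches the contig forward strand.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  case 'N': case 'n': return 'N';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_char(c);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = revcomp_str(as<std::string>(x[i]));
  }
  return out;
}

// Hamming distance with early exit once `limit` is exceeded.
static int hamming_capped(const char* a, const char* b, int n, int limit) {
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i] && ++mm > limit) return mm;
  }
  return mm;
}

struct SeedIndex {
  // k-mer code -> encoded positions ((contig << 40) | pos)
  std::unordered_map<uint64_t, std::vector<int64_t> > map;
  int k;
};

static void index_contig(SeedIndex& idx, const std::string& seq,
                         int64_t contig_i) {
  const int k = idx.k;
  const int64_t L = (int64_t)seq.size();
  uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int64_t i = 0; i < L; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      idx.map[code].push_back((contig_i << 40) | (i - k + 1));
    }
  }
}

// Collect candidate placements of `s` (already oriented) via exact k-mer
// seed lookups at every offset.
static void collect_candidates(const SeedIndex& idx, const std::string& s,
                               const std::vector<int64_t>& contig_len,
                               bool minus,
                               std::unordered_set<int64_t>& cands) {
  const int k = idx.k;
  const int64_t len = (int64_t)s.size();
  uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int64_t i = 0; i < len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      auto it = idx.map.find(code);
      if (it == idx.map.end()) continue;
      int64_t off = i - k + 1;
      for (int64_t enc : it->second) {
        int64_t contig_i = enc >> 40;
        int64_t pos = enc & ((1LL << 40) - 1);
        int64_t start = pos - off;
        if (start < 0 || start + len > contig_len[contig_i]) continue;
        // encode candidate: contig, start, strand bit
        cands.insert((contig_i << 41) | (start << 1) | (minus ? 1 : 0));
      }
    }
  }
}

static List map_one_set(const SeedIndex& idx, const SeedIndex* idx2,
                        const std::vector<std::string>& cseq,
                        const std::vector<int64_t>& clen,
                        CharacterVector reads, int k, int max_mismatch) {
  int n = reads.size();
  std::vector<int> r_read, r_contig, r_start, r_nm;
  std::vector<char> r_strand;
  int n_short = 0, n_nohit = 0, n_ambig = 0;
  std::unordered_set<int64_t> cands;
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int len = (int)fwd.size();
    if (len < k) { ++n_short; continue; }
    std::string rev = revcomp_str(fwd);
    cands.clear();
    collect_candidates(idx, fwd, clen, false, cands);
    collect_candidates(idx, rev, clen, true, cands);
    int best = max_mismatch + 1, n_best = 0;
    int64_t best_contig = -1, best_start = -1;
    bool best_minus = false;
    for (int64_t enc : cands) {
      bool minus = enc & 1;
      int64_t start = (enc >> 1) & ((1LL << 40) - 1);
      int64_t contig_i = enc >> 41;
      const std::string& s = minus ? rev : fwd;
      int mm = hamming_capped(s.data(), cseq[contig_i].data() + start, len,
                              best);
      if (mm < best) {
        best = mm; n_best = 1;
        best_contig = contig_i; best_start = start; best_minus = minus;
      } else if (mm == best) {
        ++n_best;
      }
    }
    if (best > max_mismatch && idx2) {
      // Second-chance pass with short seeds: a placement with at most
      // max_mismatch (+1) mismatches always has one clean short window
      // (pigeonhole for reads >= (max_mismatch+1) * k2), so this pass
      // restores exact equivalence with a brute-force oracle for
      // realistic reads while staying cheap.
      cands.clear();
      collect_candidates(*idx2, fwd, clen, false, cands);
      collect_candidates(*idx2, rev, clen, true, cands);
      best = max_mismatch + 1; n_best = 0;
      for (int64_t enc : cands) {
        bool minus = enc & 1;
        int64_t start = (enc >> 1) & ((1LL << 40) - 1);
        int64_t contig_i = enc >> 41;
        const std::string& s = minus ? rev : fwd;
        int mm = hamming_capped(s.data(), cseq[contig_i].data() + start,
                                len, best);
        if (mm < best) {
          best = mm; n_best = 1;
          best_contig = contig_i; best_start = start; best_minus = minus;
        } else if (mm == best) {
          ++n_best;
        }
      }
    }
    // If the short-seed pass found nothing acceptable, a full scan can
    // only confirm that: any placement with <= max_mismatch mismatches
    // of an N-free read of length >= (max_mismatch + 1) * k2 contains a
    // clean k2-window (pigeonhole) and was therefore seeded. The scan
    // is kept only for short or N-containing reads.
    bool proven_unmapped = idx2 &&
      len >= (max_mismatch + 1) * idx2->k &&
      fwd.find_first_not_of("ACGTacgt") == std::string::npos;
    if (best > max_mismatch && !proven_unmapped) {
      // Last resort: full Hamming scan (short reads, garbage reads).
      best = max_mismatch + 1; n_best = 0;
      for (int ci = 0; ci < (int)cseq.size(); ++ci) {
        for (int strand = 0; strand < 2; ++strand) {
          const std::string& s = strand ? rev : fwd;
          for (int64_t st = 0; st + len <= clen[ci]; ++st) {
            int mm = hamming_capped(s.data(), cseq[ci].data() + st, len,
                                    best);
            if (mm < best) {
              best = mm; n_best = 1;
              best_contig = ci; best_start = st; best_minus = strand;
            } else if (mm == best) {
              ++n_best;
            }
          }
        }
      }
    }
    if (best > max_mismatch) { ++n_nohit; continue; }
    if (n_best > 1) { ++n_ambig; continue; }
    r_read.push_back(r + 1);
    r_contig.push_back((int)best_contig + 1);
    r_start.push_back((int)best_start);
    r_strand.push_back(best_minus ? '-' : '+');
    r_nm.push_back(best);
  }
  int m = (int)r_read.size();
  CharacterVector strand(m);
  for (int i = 0; i < m; ++i) strand[i] = std::string(1, r_strand[i]);
  DataFrame df = DataFrame::create(
    _["read"] = wrap(r_read), _["contig"] = wrap(r_contig),
    _["start"] = wrap(r_start), _["strand"] = strand,
    _["n_mismatch"] = wrap(r_nm), _["stringsAsFactors"] = false);
  return List::create(_["alignments"] = df,
                      _["n_short"] = n_short, _["n_unmapped"] = n_nohit,
                      _["n_ambiguous"] = n_ambig);
}

// Map several read sets against one shared seed index. Each element of
// `read_sets` is a character vector of reads; returns a list of results
// in the same order (see map_one_set for the per-set contract).
// [[Rcpp::export]]
List map_read_sets_cpp(List read_sets, CharacterVector contigs,
                       int k, int max_mismatch) {
  if (k < 1 || k > 32) stop("seed length k must be in 1..32");
  int nc = contigs.size();
  std::vector<std::string> cseq(nc);
  std::vector<int64_t> clen(nc);
  SeedIndex idx; idx.k = k;
  idx.map.reserve(1 << 20);
  for (int i = 0; i < nc; ++i) {
    cseq[i] = as<std::string>(contigs[i]);
    clen[i] = (int64_t)cseq[i].size();
    index_contig(idx, cseq[i], i);
  }
  SeedIndex idx2; idx2.k = 13;
  const SeedIndex* idx2p = nullptr;
  if (k > idx2.k) {
    idx2.map.reserve(1 << 20);
    for (int i = 0; i < nc; ++i) index_contig(idx2, cseq[i], i);
    idx2p = &idx2;
  }
  List out(read_sets.size());
  for (R_xlen_t s = 0; s < read_sets.size(); ++s) {
    out[s] = map_one_set(idx, idx2p, cseq, clen,
                         as<CharacterVector>(read_sets[s]), k,
                         max_mismatch);
  }
  return out;
}

// Per-contig pileup: 4 x L matrix of A/C/G/T counts. `starts` are 0-based;
// minus-strand reads are reverse complemented before counting.
// [[Rcpp::export]]
IntegerMatrix pileup_cpp(std::string contig, IntegerVector starts,
                         CharacterVector strands, CharacterVector readseqs) {
  int64_t L = (int64_t)contig.size();
  IntegerMatrix out(4, (int)L);
  int n = starts.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(readseqs[i]);
    if (as<std::string>(strands[i]) == "-") s = revcomp_str(s);
    int64_t st = starts[i];
    int len = (int)s.size();
    if (st < 0 || st + len > L) stop("alignment out of contig bounds");
    for (int j = 0; j < len; ++j) {
      int c = base_code(s[j]);
      if (c >= 0) out(c, (int)(st + j)) += 1;
    }
  }
  return out;
}

static const char DECODE[4] = {'A', 'C', 'G', 'T'};

// Canonical k-mer profile of a read set: k-mers containing N dropped,
// counts below min_count dropped, set semantics thereafter.
// [[Rcpp::export]]
CharacterVector kmer_profile_cpp(CharacterVector reads, int k,
                                 int min_count) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(1 << 20);
  uint64_t mask = (1ULL << (2 * k)) - 1;
  int shift = 2 * (k - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    uint64_t code = 0, rcode = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; code = 0; rcode = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      rcode = (rcode >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        uint64_t canon = std::min(code, rcode);
        auto it = counts.find(canon);
        if (it == counts.end()) counts.emplace(canon, 1);
        else if (it->second < min_count) ++(it->second);
      }
    }
  }
  std::vector<uint64_t> keep;
  for (auto& kv : counts) if (kv.second >= min_count) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  CharacterVector out(keep.size());
  std::string buf(k, 'A');
  for (size_t i = 0; i < keep.size(); ++i) {
    uint64_t v = keep[i];
    for (int j = k - 1; j >= 0; --j) { buf[j] = DECODE[v & 3]; v >>= 2; }
    out[i] = buf;
  }
  return out;
}
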