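// Core sequence kernels: MinHash k-mer sketching and anchor-chain ANI.
//
// Genomes arrive as character vectors of contig sequences. Contigs are
// concatenated with a sentinel so no k-mer or alignment block can span a
// contig boundary. Only A/C/G/T (case-insensitive) participate; any other
// character breaks the current k-mer run and is never counted as identical.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// splitmix64-style finalizer; seed folded in so the whole hash family is
// reproducible (default seed 42 at the R level).
inline uint64_t mix64(uint64_t x, uint64_t seed) {
  x ^= seed + 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// reverse complement of a 2-bit packed k-mer (first base in high bits)
inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// concatenate contigs into a code vector with -1 sentinels between them
std::vector<int8_t> encode_genome(const CharacterVector& seqs, long& total_len) {
  std::vector<int8_t> codes;
  total_len = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = strlen(s);
    total_len += (long)n;
    if (i > 0) codes.push_back(-1);
    for (size_t j = 0; j < n; ++j) codes.push_back((int8_t)base_code(s[j]));
  }
  return codes;
}

struct Anchor {
  long a;       // start in genome A (concatenated coords)
  long b;       // start in genome B
  int strand;   // +1 forward, -1 reverse
  long diag;    // b - a (forward) or a + b (reverse)
};

struct Block {
  int strand;
  long diag;
  long b0, b1;  // B range [b0, b1)
  long len() const { return b1 - b0; }
  long a0(int k) const { return strand > 0 ? b0 - diag : diag + k - b1; }
};

} // namespace

// Bottom-s MinHash sketch over canonical k-mers. Returns the (at most s)
// smallest distinct hash values, scaled into [0, 2^53) so they survive the
// round trip through R doubles exactly.
// [[Rcpp::export]]
NumericVector sketch_hashes_cpp(CharacterVector seqs, int k, int s, double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (s < 1) stop("sketch size must be positive");
  const uint64_t useed = (uint64_t)seed;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  std::vector<uint64_t> hashes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* sq = CHAR(STRING_ELT(seqs, i));
    size_t n = strlen(sq);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t j = 0; j < n; ++j) {
      int c = base_code(sq[j]);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        hashes.push_back(mix64(canon, useed) >> 11);
      }
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  size_t keep = std::min((size_t)s, hashes.size());
  NumericVector out((R_xlen_t)keep);
  for (size_t i = 0; i < keep; ++i) out[i] = (double)hashes[i];
  return out;
}

// Anchor-chain ANI between two genomes.
//
// 1. shared k-mers unique in both genomes (both strands) become anchors;
// 2. anchors on the same diagonal within max_gap are merged into candidate
//    gap-free blocks;
// 3. blocks claim genome positions greedily by decreasing length (ties by
//    coordinate, symmetrically), so retained runs are one-to-one on both
//    genomes; runs shorter than min_block are dropped;
// 4. ANI = identical bp / aligned bp over retained runs; AF uses each
//    genome's total residue length as denominator.
// [[Rcpp::export]]
List align_ani_cpp(CharacterVector seqs_a, CharacterVector seqs_b,
                   int k, int max_gap, int min_block) {
  if (k < 5 || k > 31) stop("anchor k must be in [5, 31]");
  long len_a = 0, len_b = 0;
  std::vector<int8_t> A = encode_genome(seqs_a, len_a);
  std::vector<int8_t> B = encode_genome(seqs_b, len_b);
  if (len_a == 0 || len_b == 0) stop("both genomes must be non-empty");

  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;

  // count k-mer occurrences (forward scan) and remember a position
  auto build_map = [&](const std::vector<int8_t>& G,
                       std::unordered_map<uint64_t, std::pair<long, long>>& m) {
    uint64_t fwd = 0;
    int run = 0;
    for (size_t j = 0; j < G.size(); ++j) {
      int c = G[j];
      if (c < 0) { run = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        long pos = (long)j - k + 1;
        auto it = m.find(fwd);
        if (it == m.end()) m.emplace(fwd, std::make_pair(1L, pos));
        else it->second.first++;
      }
    }
  };
  std::unordered_map<uint64_t, std::pair<long, long>> mapA, mapB;
  build_map(A, mapA);
  build_map(B, mapB);

  auto occ = [](const std::unordered_map<uint64_t, std::pair<long, long>>& m,
                uint64_t code) -> long {
    auto it = m.find(code);
    return it == m.end() ? 0L : it->second.first;
  };
  // unique in the genome counting both strands
  auto unique_in = [&](const std::unordered_map<uint64_t, std::pair<long, long>>& m,
                       uint64_t code, uint64_t rc) -> bool {
    long tot = occ(m, code) + (rc == code ? 0L : occ(m, rc));
    return tot == 1L && occ(m, code) == 1L;
  };

  // scan B for anchors
  std::vector<Anchor> anchors;
  {
    uint64_t fwd = 0;
    int run = 0;
    for (size_t j = 0; j < B.size(); ++j) {
      int c = B[j];
      if (c < 0) { run = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        long posB = (long)j - k + 1;
        uint64_t rc = revcomp_code(fwd, k);
        if (!unique_in(mapB, fwd, rc)) continue;
        if (unique_in(mapA, fwd, rc)) {
          long posA = mapA[fwd].second;
          anchors.push_back({posA, posB, +1, posB - posA});
        } else if (rc != fwd && unique_in(mapA, rc, fwd)) {
          long posA = mapA[rc].second;
          anchors.push_back({posA, posB, -1, posA + posB});
        }
      }
    }
  }

  List out = List::create(
      _["ani"] = 0.0, _["af_query"] = 0.0, _["af_target"] = 0.0,
      _["aligned_bp"] = 0.0, _["identical_bp"] = 0.0, _["n_blocks"] = 0);
  if (anchors.empty()) return out;

  std::sort(anchors.begin(), anchors.end(), [](const Anchor& x, const Anchor& y) {
    if (x.strand != y.strand) return x.strand > y.strand;
    if (x.diag != y.diag) return x.diag < y.diag;
    return x.b < y.b;
  });

  // merge same-diagonal anchors within max_gap
  std::vector<Block> blocks;
  Block cur{anchors[0].strand, anchors[0].diag, anchors[0].b, anchors[0].b + k};
  for (size_t i = 1; i < anchors.size(); ++i) {
    const Anchor& an = anchors[i];
    if (an.strand == cur.strand && an.diag == cur.diag &&
        an.b - cur.b1 <= (long)max_gap) {
      if (an.b + k > cur.b1) cur.b1 = an.b + k;
    } else {
      blocks.push_back(cur);
      cur = Block{an.strand, an.diag, an.b, an.b + k};
    }
  }
  blocks.push_back(cur);

  // longest blocks claim positions first; symmetric tie-break so that
  // swapping the two genomes yields the same retained runs
  std::sort(blocks.begin(), blocks.end(), [&](const Block& x, const Block& y) {
    if (x.len() != y.len()) return x.len() > y.len();
    long xmin = std::min(x.a0(k), x.b0), ymin = std::min(y.a0(k), y.b0);
    if (xmin != ymin) return xmin < ymin;
    long xmax = std::max(x.a0(k), x.b0), ymax = std::max(y.a0(k), y.b0);
    if (xmax != ymax) return xmax < ymax;
    return x.strand > y.strand;
  });

  std::vector<uint8_t> usedA(A.size(), 0), usedB(B.size(), 0);
  double aligned = 0.0, ident = 0.0;
  long n_runs = 0;

  for (const Block& bl : blocks) {
    long run_start = -1;
    for (long q = bl.b0; q <= bl.b1; ++q) {
      bool free_pos = false;
      long pa = 0;
      if (q < bl.b1) {
        pa = bl.strand > 0 ? q - bl.diag : bl.diag + k - 1 - q;
        free_pos = pa >= 0 && pa < (long)A.size() && A[pa] >= 0 && B[q] >= 0 &&
                   !usedA[pa] && !usedB[q];
      }
      if (free_pos) {
        if (run_start < 0) run_start = q;
      } else if (run_start >= 0) {
        long rlen = q - run_start;
        if (rlen >= (long)min_block) {
          ++n_runs;
          for (long qq = run_start; qq < q; ++qq) {
            long pq = bl.strand > 0 ? qq - bl.diag : bl.diag + k - 1 - qq;
            usedA[pq] = 1;
            usedB[qq] = 1;
            aligned += 1.0;
            int cb = B[qq];
            int ca = A[pq];
            int want = bl.strand > 0 ? cb : 3 - cb;
            if (ca == want) ident += 1.0;
          }
        }
        run_start = -1;
      }
    }
  }

  out["ani"] = aligned > 0 ? ident / aligned : 0.0;
  out["af_query"] = aligned / (double)len_a;
  out["af_target"] = aligned / (double)len_b;
  out["aligned_bp"] = aligned;
  out["identical_bp"] = ident;
  out["n_blocks"] = (int)n_runs;
  return out;
}
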