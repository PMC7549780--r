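// Dual-genome k-mer seed-and-verify read mapper.
//
// Both parental transcriptomes are indexed by exact k-mers of their forward
// strands; a read is queried as-is (+) and as its reverse complement (-), so
// both strands are covered. Every candidate location reachable by any exact
// k-mer seed is verified by a full-length ungapped (Hamming) comparison.
// Substitution-only divergence between the two references keeps coordinates
// comparable across genomes, so gapped alignment is not needed.

#include <Rcpp.h>
#include <climits>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N or invalid: never part of an exact seed
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// packed hit: genome (1 bit) << 48 | gene << 24 | pos
static inline uint64_t pack_hit(int genome, int gene, int pos) {
  return (static_cast<uint64_t>(genome) << 48) |
         (static_cast<uint64_t>(gene) << 24) |
         static_cast<uint64_t>(pos);
}

struct DualIndex {
  int k;
  std::vector<std::string> gene_ids;
  std::vector<std::string> seq[2]; // [0]=A, [1]=B, forward strands
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
  std::vector<long> kmer_count[2]; // forward k-mer positions recorded per gene
};

// [[Rcpp::export]]
SEXP dual_index_build(CharacterVector gene_ids, CharacterVector seq_a,
                      CharacterVector seq_b, int k) {
  if (k < 8 || k > 31)
    stop("k must be between 8 and 31");
  if (gene_ids.size() != seq_a.size() || gene_ids.size() != seq_b.size())
    stop("gene_ids, seq_a and seq_b must have equal length");
  DualIndex* idx = new DualIndex();
  idx->k = k;
  int n = gene_ids.size();
  idx->gene_ids.reserve(n);
  for (int i = 0; i < n; ++i)
    idx->gene_ids.push_back(as<std::string>(gene_ids[i]));
  for (int g = 0; g < 2; ++g) {
    CharacterVector src = (g == 0) ? seq_a : seq_b;
    idx->seq[g].reserve(n);
    idx->kmer_count[g].assign(n, 0);
    for (int i = 0; i < n; ++i)
      idx->seq[g].push_back(as<std::string>(src[i]));
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int g = 0; g < 2; ++g) {
    for (int i = 0; i < n; ++i) {
      const std::string& s = idx->seq[g][i];
      if ((int)s.size() < k) continue;
      uint64_t key = 0;
      int valid = 0; // bases accumulated since last invalid one
      for (size_t p = 0; p < s.size(); ++p) {
        int c = base_code(s[p]);
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | static_cast<uint64_t>(c)) & mask;
        if (++valid >= k) {
          int start = static_cast<int>(p) - k + 1;
          idx->table[key].push_back(pack_hit(g, i, start));
          idx->kmer_count[g][i]++;
        }
      }
    }
  }
  XPtr<DualIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
DataFrame dual_index_stats(SEXP xp) {
  XPtr<DualIndex> idx(xp);
  int n = idx->gene_ids.size();
  CharacterVector genome(2 * n), gene(2 * n);
  IntegerVector count(2 * n), length(2 * n);
  for (int g = 0; g < 2; ++g) {
    for (int i = 0; i < n; ++i) {
      int row = g * n + i;
      genome[row] = (g == 0) ? "A" : "B";
      gene[row] = idx->gene_ids[i];
      count[row] = idx->kmer_count[g][i];
      length[row] = idx->seq[g][i].size();
    }
  }
  return DataFrame::create(_["genome"] = genome, _["gene_id"] = gene,
                           _["length"] = length, _["n_kmers"] = count);
}

// [[Rcpp::export]]
int dual_index_k(SEXP xp) {
  XPtr<DualIndex> idx(xp);
  return idx->k;
}

struct Hit {
  int gene;
  int pos;
  char strand; // '+' read matches forward; '-' revcomp matches forward
  int mm;
};

// Hamming verification; N (or any non-ACGT) in the query mismatches everywhere.
static inline int hamming_capped(const std::string& ref, int start,
                                 const std::string& query, int cap) {
  int mm = 0;
  for (size_t i = 0; i < query.size(); ++i) {
    char q = query[i];
    int qc = base_code(q);
    if (qc < 0 || base_code(ref[start + i]) != qc) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

static void map_one(const DualIndex* idx, const std::string& read, int genome,
                    int max_mm, std::vector<Hit>& out) {
  const int k = idx->k;
  const int L = read.size();
  if (L < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_set<uint64_t> seen; // dedupe (gene, start, strand)
  for (int strand = 0; strand < 2; ++strand) {
    std::string q = (strand == 0) ? read : revcomp(read);
    uint64_t key = 0;
    int valid = 0;
    for (int p = 0; p < L; ++p) {
      int c = base_code(q[p]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | static_cast<uint64_t>(c)) & mask;
      if (++valid < k) continue;
      int off = p - k + 1;
      auto it = idx->table.find(key);
      if (it == idx->table.end()) continue;
      for (uint64_t packed : it->second) {
        int g = static_cast<int>(packed >> 48);
        if (g != genome) continue;
        int gene = static_cast<int>((packed >> 24) & 0xFFFFFF);
        int pos = static_cast<int>(packed & 0xFFFFFF);
        int start = pos - off;
        const std::string& ref = idx->seq[genome][gene];
        if (start < 0 || start + L > (int)ref.size()) continue;
        uint64_t sig = (static_cast<uint64_t>(gene) << 32) |
                       (static_cast<uint64_t>(start) << 1) |
                       static_cast<uint64_t>(strand);
        if (!seen.insert(sig).second) continue;
        int mm = hamming_capped(ref, start, q, max_mm);
        if (mm <= max_mm)
          out.push_back({gene, start, strand == 0 ? '+' : '-', mm});
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame map_read_cpp(SEXP xp, std::string read, std::string genome,
                       int max_mismatches) {
  XPtr<DualIndex> idx(xp);
  int g = (genome == "A") ? 0 : 1;
  std::vector<Hit> hits;
  map_one(idx, read, g, max_mismatches, hits);
  int n = hits.size();
  CharacterVector gene(n), strand(n);
  IntegerVector pos(n), mm(n);
  for (int i = 0; i < n; ++i) {
    gene[i] = idx->gene_ids[hits[i].gene];
    pos[i] = hits[i].pos;
    strand[i] = std::string(1, hits[i].strand);
    mm[i] = hits[i].mm;
  }
  return DataFrame::create(_["gene_id"] = gene, _["pos"] = pos,
                           _["strand"] = strand, _["mismatches"] = mm);
}

struct PairRes {
  int status; // 0 none, 1 unique, 2 multi
  int gene, fwd_pos, rev_pos, mm1, mm2;
  char strand1; // strand of mate1 in the winning pairing
};

// Best-mismatch concordant pairing within one genome. Concordance: same gene,
// opposite strands, FR orientation (forward mate left of reverse mate) and
// fragment span within [fmin, fmax]. "Multi-mapped" = more than one distinct
// location at the best total mismatch count.
static PairRes pair_in_genome(const std::vector<Hit>& h1,
                              const std::vector<Hit>& h2,
                              int len1, int len2, int fmin, int fmax) {
  PairRes res{0, -1, -1, -1, -1, -1, '+'};
  int best = INT_MAX;
  int n_best = 0;
  int bg = -1, bf = -1, br = -1, bm1 = -1, bm2 = -1;
  char bs1 = '+';
  for (const Hit& a : h1) {
    for (const Hit& b : h2) {
      if (a.gene != b.gene || a.strand == b.strand) continue;
      const Hit& fwd = (a.strand == '+') ? a : b;
      const Hit& rev = (a.strand == '+') ? b : a;
      int rev_len = (a.strand == '+') ? len2 : len1;
      if (rev.pos < fwd.pos) continue;
      int span = rev.pos + rev_len - fwd.pos;
      if (span < fmin || span > fmax) continue;
      int tot = a.mm + b.mm;
      if (tot < best) {
        best = tot;
        n_best = 1;
        bg = a.gene; bf = fwd.pos; br = rev.pos;
        bm1 = a.mm; bm2 = b.mm; bs1 = a.strand;
      } else if (tot == best) {
        if (a.gene != bg || fwd.pos != bf || rev.pos != br)
          n_best++;
      }
    }
  }
  if (n_best == 0) return res;
  res.status = (n_best > 1) ? 2 : 1;
  res.gene = bg; res.fwd_pos = bf; res.rev_pos = br;
  res.mm1 = bm1; res.mm2 = bm2; res.strand1 = bs1;
  return res;
}

// mode: "hybrid" consults both genomes; "parental_A"/"parental_B" consult one.
// [[Rcpp::export]]
DataFrame classify_pairs_cpp(SEXP xp, CharacterVector reads1,
                             CharacterVector reads2, std::string mode,
                             int max_mismatches, int fragment_min,
                             int fragment_max) {
  XPtr<DualIndex> idx(xp);
  if (reads1.size() != reads2.size())
    stop("mate files differ in read count");
  bool useA = (mode == "hybrid" || mode == "parental_A");
  bool useB = (mode == "hybrid" || mode == "parental_B");
  if (!useA && !useB)
    stop("mode must be one of 'hybrid', 'parental_A', 'parental_B'");
  int n = reads1.size();
  CharacterVector call(n), reason(n), gene(n), genome(n), strand1(n);
  IntegerVector fwd_pos(n), rev_pos(n), mm1(n), mm2(n);
  for (int i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(reads1[i]);
    std::string r2 = as<std::string>(reads2[i]);
    std::vector<Hit> h1A, h2A, h1B, h2B;
    if (useA) { map_one(idx, r1, 0, max_mismatches, h1A);
                map_one(idx, r2, 0, max_mismatches, h2A); }
    if (useB) { map_one(idx, r1, 1, max_mismatches, h1B);
                map_one(idx, r2, 1, max_mismatches, h2B); }
    PairRes pA{0,-1,-1,-1,-1,-1,'+'}, pB{0,-1,-1,-1,-1,-1,'+'};
    if (useA) pA = pair_in_genome(h1A, h2A, r1.size(), r2.size(),
                                  fragment_min, fragment_max);
    if (useB) pB = pair_in_genome(h1B, h2B, r1.size(), r2.size(),
                                  fragment_min, fragment_max);
    gene[i] = NA_STRING; genome[i] = NA_STRING; reason[i] = NA_STRING;
    strand1[i] = NA_STRING;
    fwd_pos[i] = NA_INTEGER; rev_pos[i] = NA_INTEGER;
    mm1[i] = NA_INTEGER; mm2[i] = NA_INTEGER;
    auto fill = [&](const PairRes& p, const char* gname) {
      gene[i] = idx->gene_ids[p.gene];
      genome[i] = gname;
      fwd_pos[i] = p.fwd_pos; rev_pos[i] = p.rev_pos;
      mm1[i] = p.mm1; mm2[i] = p.mm2;
      strand1[i] = std::string(1, p.strand1);
    };
    if (pA.status == 2 || pB.status == 2) {
      call[i] = "discarded"; reason[i] = "multimapped";
    } else if (pA.status == 1 && pB.status == 1) {
      call[i] = "common"; fill(pA, "AB");
    } else if (pA.status == 1) {
      call[i] = "A_specific"; fill(pA, "A");
    } else if (pB.status == 1) {
      call[i] = "B_specific"; fill(pB, "B");
    } else {
      bool m1 = (!h1A.empty() || !h1B.empty());
      bool m2 = (!h2A.empty() || !h2B.empty());
      call[i] = "discarded";
      if (!m1 && !m2) reason[i] = "unmapped";
      else if (m1 != m2) reason[i] = "orphan";
      else reason[i] = "discordant";
    }
  }
  return DataFrame::create(
      _["call"] = call, _["reason"] = reason, _["genome"] = genome,
      _["gene_id"] = gene, _["fwd_pos"] = fwd_pos, _["rev_pos"] = rev_pos,
      _["strand1"] = strand1, _["mm1"] = mm1, _["mm2"] = mm2,
      _["stringsAsFactors"] = false);
}
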