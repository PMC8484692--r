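// k-mer index and read-assignment engine.
//
// Genes are indexed by canonical (strand-min) 2-bit-encoded k-mers held in an
// open-addressed hash table (interleaved key/value slots, linear probing,
// software prefetch for the batch of k-mers of each read).  A read votes for
// the gene(s) hit by the plurality of its k-mers; ties are split
// fractionally.  The positional entry point replays the identical voting
// kernel on windows of the stored gene sequences, so strand handling and
// tie-breaking are shared by construction.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

namespace {

static int8_t CODES[256];
static bool codes_ready = false;
static void init_codes() {
  if (codes_ready) return;
  for (int i = 0; i < 256; ++i) CODES[i] = -1;
  CODES[(unsigned char)'A'] = 0; CODES[(unsigned char)'a'] = 0;
  CODES[(unsigned char)'C'] = 1; CODES[(unsigned char)'c'] = 1;
  CODES[(unsigned char)'G'] = 2; CODES[(unsigned char)'g'] = 2;
  CODES[(unsigned char)'T'] = 3; CODES[(unsigned char)'t'] = 3;
  codes_ready = true;
}

struct Slot {
  uint64_t key;
  int32_t val;   // -1 empty; >= 0 gene id; <= -2 multi-list slot -(val+2)
  int32_t pad;
};

struct KmerIndex {
  int k;
  int n_genes;
  uint64_t mask;
  size_t tsize;  // power of two
  std::vector<Slot> slots;
  std::vector<std::vector<int32_t>> multi;
  std::vector<std::vector<int8_t>> gene_codes;
};

inline size_t hash64(uint64_t x) {
  x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return (size_t)x;
}

// returns slot index or -1
inline long lookup(const KmerIndex& idx, uint64_t key, size_t h0) {
  size_t h = h0;
  while (idx.slots[h].val != -1) {
    if (idx.slots[h].key == key) return (long)h;
    h = (h + 1) & (idx.tsize - 1);
  }
  return -1;
}

inline void insert(KmerIndex& idx, uint64_t key, int32_t gene) {
  size_t h = hash64(key) & (idx.tsize - 1);
  while (idx.slots[h].val != -1) {
    if (idx.slots[h].key == key) {
      int32_t v = idx.slots[h].val;
      if (v >= 0) {
        if (v == gene) return;
        idx.multi.push_back(std::vector<int32_t>{v, gene});
        idx.slots[h].val = -(int32_t)idx.multi.size() - 1;
      } else {
        std::vector<int32_t>& lst = idx.multi[-(v + 2)];
        if (std::find(lst.begin(), lst.end(), gene) == lst.end())
          lst.push_back(gene);
      }
      return;
    }
    h = (h + 1) & (idx.tsize - 1);
  }
  idx.slots[h].key = key;
  idx.slots[h].val = gene;
}

// dense per-gene vote buffer with a touched-gene list: O(1) per hit
struct VoteAcc {
  std::vector<int32_t> buf;       // per-gene hit counts (dense)
  std::vector<int32_t> touched;   // genes with buf > 0
  int hits = 0;
  void init(int n_genes) { buf.assign(n_genes, 0); touched.clear(); hits = 0; }
  inline void add(int32_t g) {
    ++hits;
    if (buf[g]++ == 0) touched.push_back(g);
  }
  void reset() {
    for (int32_t g : touched) buf[g] = 0;
    touched.clear();
    hits = 0;
  }
};

// collect the canonical k-mers of a base-code window into `keys`
inline void collect_kmers(const KmerIndex& idx, const int8_t* codes, int len,
                          std::vector<uint64_t>& keys) {
  keys.clear();
  const int k = idx.k;
  if (len < k) return;
  uint64_t fwd = 0, rev = 0;
  const int shift = 2 * (k - 1);
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    int8_t c = codes[i];
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & idx.mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) keys.push_back(fwd < rev ? fwd : rev);
  }
}

// prefetch + lookup all keys, feeding the vote accumulator
inline void vote_keys(const KmerIndex& idx, const std::vector<uint64_t>& keys,
                      std::vector<size_t>& h0, VoteAcc& acc) {
  const size_t n = keys.size();
  h0.resize(n);
  for (size_t i = 0; i < n; ++i) {
    h0[i] = hash64(keys[i]) & (idx.tsize - 1);
    __builtin_prefetch(&idx.slots[h0[i]], 0, 1);
  }
  for (size_t i = 0; i < n; ++i) {
    long s = lookup(idx, keys[i], h0[i]);
    if (s >= 0) {
      int32_t v = idx.slots[s].val;
      if (v >= 0) acc.add(v);
      else for (int32_t g : idx.multi[-(v + 2)]) acc.add(g);
    }
  }
}

inline void encode(const char* s, int len, std::vector<int8_t>& out) {
  out.resize(len);
  for (int i = 0; i < len; ++i) out[i] = CODES[(unsigned char)s[i]];
}

// distribute one read's vote; returns true if the read had any hit
inline bool settle(const VoteAcc& acc, std::vector<double>& counts) {
  if (acc.hits == 0 || acc.touched.empty()) return false;
  int32_t best = 0;
  for (int32_t g : acc.touched) best = std::max(best, acc.buf[g]);
  int ntop = 0;
  for (int32_t g : acc.touched) if (acc.buf[g] == best) ++ntop;
  const double w = 1.0 / ntop;
  for (int32_t g : acc.touched)
    if (acc.buf[g] == best) counts[g] += w;
  return true;
}

} // namespace

// [[Rcpp::export]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
  init_codes();
  if (k < 1 || k > 31) stop("k must be in 1..31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->n_genes = seqs.size();
  idx->mask = (1ULL << (2 * k)) - 1;
  size_t total = 0;
  idx->gene_codes.resize(seqs.size());
  for (int g = 0; g < seqs.size(); ++g) {
    const char* s = CHAR(STRING_ELT(seqs, g));
    int len = (int)LENGTH(STRING_ELT(seqs, g));
    encode(s, len, idx->gene_codes[g]);
    if (len >= k) total += (size_t)(len - k + 1);
  }
  size_t ts = 16;
  while (ts < 2 * total + 16) ts <<= 1;
  idx->tsize = ts;
  idx->slots.assign(ts, Slot{0, -1, 0});
  for (int g = 0; g < (int)idx->gene_codes.size(); ++g) {
    const std::vector<int8_t>& codes = idx->gene_codes[g];
    int len = (int)codes.size();
    if (len < k) continue;
    uint64_t fwd = 0, rev = 0;
    const int shift = 2 * (k - 1);
    int valid = 0;
    for (int i = 0; i < len; ++i) {
      int8_t c = codes[i];
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & idx->mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) insert(*idx, fwd < rev ? fwd : rev, g);
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector kmer_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return IntegerVector::create(_["k"] = idx->k, _["n_genes"] = idx->n_genes);
}

// Per-gene fractional counts for a vector of reads (string path).
// [[Rcpp::export]]
NumericVector kmer_count_reads(SEXP xp, CharacterVector reads) {
  init_codes();
  XPtr<KmerIndex> idx(xp);
  std::vector<double> counts(idx->n_genes, 0.0);
  std::vector<int8_t> codes;
  std::vector<uint64_t> keys;
  std::vector<size_t> h0;
  VoteAcc acc;
  acc.init(idx->n_genes);
  int assigned = 0;
  for (int r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    encode(s, len, codes);
    collect_kmers(*idx, codes.data(), len, keys);
    acc.reset();
    vote_keys(*idx, keys, h0, acc);
    if (settle(acc, counts)) ++assigned;
  }
  NumericVector out(counts.begin(), counts.end());
  out.attr("n_assigned") = assigned;
  return out;
}

// Per-read assignment detail (gene ids 1-based and weights), for inspection
// and unit tests on small inputs.
// [[Rcpp::export]]
List kmer_assign_detail(SEXP xp, CharacterVector reads) {
  init_codes();
  XPtr<KmerIndex> idx(xp);
  std::vector<int> out_read, out_gene;
  std::vector<double> out_w;
  std::vector<int8_t> codes;
  std::vector<uint64_t> keys;
  std::vector<size_t> h0;
  VoteAcc acc;
  acc.init(idx->n_genes);
  for (int r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    encode(s, len, codes);
    collect_kmers(*idx, codes.data(), len, keys);
    acc.reset();
    vote_keys(*idx, keys, h0, acc);
    if (acc.hits == 0 || acc.touched.empty()) continue;
    std::vector<int32_t> tg(acc.touched);
    std::sort(tg.begin(), tg.end());
    int32_t best = 0;
    for (int32_t g : tg) best = std::max(best, acc.buf[g]);
    int ntop = 0;
    for (int32_t g : tg) if (acc.buf[g] == best) ++ntop;
    for (int32_t g : tg) {
      if (acc.buf[g] != best) continue;
      out_read.push_back(r + 1);
      out_gene.push_back(g + 1);
      out_w.push_back(1.0 / ntop);
    }
  }
  return List::create(_["read"] = wrap(out_read), _["gene"] = wrap(out_gene),
                      _["weight"] = wrap(out_w));
}

// Positional fast path: reads are length-`read_len` windows of indexed genes
// (1-based gene id and start).  Strand is irrelevant because votes use
// canonical k-mers.
// [[Rcpp::export]]
NumericVector kmer_count_positions(SEXP xp, IntegerVector gene,
                                   IntegerVector start, int read_len) {
  XPtr<KmerIndex> idx(xp);
  if (gene.size() != start.size()) stop("gene and start lengths differ");
  std::vector<double> counts(idx->n_genes, 0.0);
  std::vector<uint64_t> keys;
  std::vector<size_t> h0;
  VoteAcc acc;
  acc.init(idx->n_genes);
  int assigned = 0;
  for (int r = 0; r < gene.size(); ++r) {
    int g = gene[r] - 1;
    if (g < 0 || g >= idx->n_genes) stop("gene id out of range");
    const std::vector<int8_t>& codes = idx->gene_codes[g];
    int s0 = start[r] - 1;
    int len = std::min((int)codes.size() - s0, read_len);
    if (s0 < 0 || len < 1) stop("read window outside gene");
    collect_kmers(*idx, codes.data() + s0, len, keys);
    acc.reset();
    vote_keys(*idx, keys, h0, acc);
    if (settle(acc, counts)) ++assigned;
  }
  NumericVector out(counts.begin(), counts.end());
  out.attr("n_assigned") = assigned;
  return out;
}

// Number of DISTINCT k-mers of each read (canonical, either strand) present
// in the index.  Used for decoy matching in the QC cascade.
// [[Rcpp::export]]
IntegerVector kmer_distinct_hits(SEXP xp, CharacterVector reads) {
  init_codes();
  XPtr<KmerIndex> idx(xp);
  IntegerVector out(reads.size());
  std::vector<int8_t> codes;
  std::vector<uint64_t> keys;
  std::vector<size_t> h0;
  std::vector<uint64_t> hitk;
  for (int r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    encode(s, len, codes);
    collect_kmers(*idx, codes.data(), len, keys);
    const size_t n = keys.size();
    h0.resize(n);
    for (size_t i = 0; i < n; ++i) {
      h0[i] = hash64(keys[i]) & (idx->tsize - 1);
      __builtin_prefetch(&idx->slots[h0[i]], 0, 1);
    }
    hitk.clear();
    for (size_t i = 0; i < n; ++i)
      if (lookup(*idx, keys[i], h0[i]) >= 0) hitk.push_back(keys[i]);
    std::sort(hitk.begin(), hitk.end());
    out[r] = (int)(std::unique(hitk.begin(), hitk.end()) - hitk.begin());
  }
  return out;
}

// Precompute the voting result of every admissible read window (gene,
// start) of the indexed genes, using the identical collect/vote/settle
// kernel.  Returns flat arrays: per-gene number of admissible starts, and
// per-position offsets into a concatenated top-gene list (ties share the
// position's vote equally).
// [[Rcpp::export]]
List kmer_position_map(SEXP xp, int read_len) {
  XPtr<KmerIndex> idx(xp);
  const int ng = idx->n_genes;
  std::vector<int> n_starts(ng);
  long total = 0;
  for (int g = 0; g < ng; ++g) {
    int len = (int)idx->gene_codes[g].size();
    n_starts[g] = len >= read_len ? len - read_len + 1 : 0;
    total += n_starts[g];
  }
  std::vector<int> top_off;
  top_off.reserve(total + 1);
  top_off.push_back(0);
  std::vector<int> top_genes;
  top_genes.reserve(total);
  std::vector<uint64_t> keys;
  std::vector<size_t> h0;
  VoteAcc acc;
  acc.init(ng);
  for (int g = 0; g < ng; ++g) {
    const std::vector<int8_t>& codes = idx->gene_codes[g];
    for (int s = 0; s < n_starts[g]; ++s) {
      collect_kmers(*idx, codes.data() + s, read_len, keys);
      acc.reset();
      vote_keys(*idx, keys, h0, acc);
      if (acc.hits > 0 && !acc.touched.empty()) {
        int32_t best = 0;
        for (int32_t t : acc.touched) best = std::max(best, acc.buf[t]);
        std::vector<int32_t> tg;
        for (int32_t t : acc.touched) if (acc.buf[t] == best) tg.push_back(t);
        std::sort(tg.begin(), tg.end());
        for (int32_t t : tg) top_genes.push_back(t + 1);
      }
      top_off.push_back((int)top_genes.size());
    }
  }
  return List::create(_["n_starts"] = wrap(n_starts),
                      _["top_off"] = wrap(top_off),
                      _["top_genes"] = wrap(top_genes),
                      _["read_len"] = read_len);
}

// Count reads described by (gene, start) through a precomputed position
// map.  Equals per-read voting by construction.
// [[Rcpp::export]]
NumericVector kmer_count_mapped(List map, IntegerVector gene,
                                IntegerVector start) {
  IntegerVector n_starts = map["n_starts"];
  IntegerVector top_off = map["top_off"];
  IntegerVector top_genes = map["top_genes"];
  const int ng = n_starts.size();
  std::vector<long> gene_off(ng + 1, 0);
  for (int g = 0; g < ng; ++g) gene_off[g + 1] = gene_off[g] + n_starts[g];
  std::vector<double> counts(ng, 0.0);
  long assigned = 0;
  for (int r = 0; r < gene.size(); ++r) {
    int g = gene[r] - 1;
    if (g < 0 || g >= ng) stop("gene id out of range");
    int s = start[r] - 1;
    if (s < 0 || s >= n_starts[g]) stop("read window outside gene");
    long p = gene_off[g] + s;
    int a = top_off[p], b = top_off[p + 1];
    if (b > a) {
      ++assigned;
      double w = 1.0 / (b - a);
      for (int t = a; t < b; ++t) counts[top_genes[t] - 1] += w;
    }
  }
  NumericVector out(counts.begin(), counts.end());
  out.attr("n_assigned") = (double)assigned;
  return out;
}
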