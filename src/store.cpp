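// k-mer hash store and virtual-primer search.
//
// Sequences are indexed by every exact 10-mer position on both strands; a
// 20-bp primer (possibly carrying IUPAC ambiguity codes) is located by the
// pigeonhole split into two 10-mer halves, each expanded to at most 16 exact
// keys, then verified over the full 20 positions under IUPAC set matching.
// Any occurrence with <= 1 mismatch has at least one exact half, so the
// 1-mismatch search is complete.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const int K = 10;

// pattern masks: IUPAC codes denote base sets (N = any); read masks: A/C/G/T
// only — an 'N' in a read matches nothing.
static int PAT[256];
static int RD[256];

static void init_tables() {
  static bool done = false;
  if (done) return;
  for (int i = 0; i < 256; ++i) { PAT[i] = 0; RD[i] = 0; }
  PAT['A'] = 1; PAT['C'] = 2; PAT['G'] = 4; PAT['T'] = 8;
  PAT['M'] = 3; PAT['R'] = 5; PAT['S'] = 6; PAT['V'] = 7;
  PAT['W'] = 9; PAT['Y'] = 10; PAT['H'] = 11; PAT['K'] = 12;
  PAT['D'] = 13; PAT['B'] = 14; PAT['N'] = 15;
  RD['A'] = 1; RD['C'] = 2; RD['G'] = 4; RD['T'] = 8;
  done = true;
}

static inline int twobit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static const char RCC[256] = {0};
static inline char rc_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
    case 'T': return 'A'; case 'R': return 'Y'; case 'Y': return 'R';
    case 'K': return 'M'; case 'M': return 'K'; case 'S': return 'S';
    case 'W': return 'W'; case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
  }
  return 'N';
}

static std::string rc_string(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = rc_char(c);
  return out;
}

struct SeqStore {
  std::vector<std::string> fwd;  // as given
  std::vector<std::string> rev;  // reverse complements
  // key (2-bit packed 10-mer) -> packed entries: seq<<33 | pos<<1 | strand
  std::unordered_map<uint32_t, std::vector<uint64_t>> idx;
};

static void index_seq(SeqStore& st, const std::string& s, uint64_t si,
                      int strand) {
  const int n = (int)s.size();
  if (n < K) return;
  uint32_t key = 0;
  int valid = 0;  // length of current run of A/C/G/T
  for (int i = 0; i < n; ++i) {
    int b = twobit(s[i]);
    if (b < 0) {
      valid = 0;
      key = 0;
      continue;
    }
    key = ((key << 2) | (uint32_t)b) & 0xFFFFFu;
    if (++valid >= K) {
      uint64_t pos = (uint64_t)(i - K + 1);
      st.idx[key].push_back((si << 33) | (pos << 1) | (uint64_t)strand);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_store_build(CharacterVector seqs, int min_len) {
  init_tables();
  SeqStore* st = new SeqStore();
  const int n = seqs.size();
  st->fwd.reserve(n);
  st->rev.reserve(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    st->fwd.push_back(s);
    st->rev.push_back(rc_string(s));
  }
  for (int i = 0; i < n; ++i) {
    if ((int)st->fwd[i].size() < min_len) continue;
    index_seq(*st, st->fwd[i], (uint64_t)i, 0);
    index_seq(*st, st->rev[i], (uint64_t)i, 1);
  }
  XPtr<SeqStore> p(st, true);
  return p;
}

// [[Rcpp::export]]
int cpp_store_size(SEXP ptr) {
  XPtr<SeqStore> st(ptr);
  return (int)st->fwd.size();
}

// expand one 10-mer half of an IUPAC pattern into exact 2-bit keys;
// more than two ambiguous positions -> no keys from this half.
static bool expand_half(const std::string& half, std::vector<uint32_t>& keys) {
  int namb = 0;
  for (char c : half) {
    int m = PAT[(unsigned char)c];
    if (m == 0) return false;  // unmatchable character
    int pc = __builtin_popcount((unsigned)m);
    if (pc > 1) ++namb;
  }
  if (namb > 2) return false;
  keys.clear();
  keys.push_back(0u);
  for (char c : half) {
    int m = PAT[(unsigned char)c];
    std::vector<uint32_t> next;
    next.reserve(keys.size() * 4);
    for (int b = 0; b < 4; ++b) {
      if (!(m & (1 << b))) continue;
      for (uint32_t k : keys) next.push_back((k << 2) | (uint32_t)b);
    }
    keys.swap(next);
  }
  return true;
}

static inline int count_mm(const std::string& read, int off,
                           const std::string& primer, int budget) {
  int mm = 0;
  const int L = (int)primer.size();
  for (int j = 0; j < L; ++j) {
    if (!(PAT[(unsigned char)primer[j]] & RD[(unsigned char)read[off + j]])) {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_find_primer(SEXP ptr, std::string primer, int max_mismatch) {
  init_tables();
  XPtr<SeqStore> st(ptr);
  const int L = (int)primer.size();
  std::unordered_set<uint64_t> seen;
  std::vector<int> r_seq, r_off, r_mm;
  std::vector<int> r_strand;
  std::vector<uint32_t> keys;
  for (int h = 0; h + K <= L; h += K) {
    if (!expand_half(primer.substr(h, K), keys)) continue;
    for (uint32_t key : keys) {
      auto it = st->idx.find(key);
      if (it == st->idx.end()) continue;
      for (uint64_t e : it->second) {
        int si = (int)(e >> 33);
        int strand = (int)(e & 1u);
        int pos = (int)((e >> 1) & 0xFFFFFFFFu);
        int off = pos - h;
        if (off < 0) continue;
        const std::string& s = strand ? st->rev[si] : st->fwd[si];
        if (off + L > (int)s.size()) continue;
        uint64_t tag = ((uint64_t)si << 33) | ((uint64_t)off << 1) |
                       (uint64_t)strand;
        if (seen.count(tag)) continue;
        int mm = count_mm(s, off, primer, max_mismatch);
        if (mm <= max_mismatch) {
          seen.insert(tag);
          r_seq.push_back(si + 1);
          r_strand.push_back(strand ? -1 : 1);
          r_off.push_back(off);
          r_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = r_seq, _["strand"] = r_strand,
                           _["offset"] = r_off, _["mismatches"] = r_mm,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_oriented_seq(SEXP ptr, IntegerVector seq_idx,
                                 IntegerVector strand) {
  XPtr<SeqStore> st(ptr);
  const int n = seq_idx.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    int si = seq_idx[i] - 1;
    out[i] = (strand[i] < 0) ? st->rev[si] : st->fwd[si];
  }
  return out;
}

// Map full reads onto stored (contig) sequences: seeds are the read's exact
// 10-mers at offsets 0, 10, 20, ... plus the final window; a placement is
// kept when the read lies entirely within the contig and carries at most
// `max_mismatch` penalized mismatches, a mismatch at a read position with
// quality < qmin being free. Each read reports the distinct contigs hit.
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP ptr, CharacterVector reads, CharacterVector quals,
                        int max_mismatch, int qmin) {
  init_tables();
  XPtr<SeqStore> st(ptr);
  std::vector<int> o_read, o_contig;
  std::vector<int> seeds;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    std::string qu = as<std::string>(quals[ri]);
    const int n = (int)rd.size();
    if (n < K || (int)qu.size() != n) continue;
    seeds.clear();
    for (int o = 0; o + K <= n; o += K) seeds.push_back(o);
    if (seeds.empty() || seeds.back() != n - K) seeds.push_back(n - K);
    std::unordered_set<int> contigs;
    std::unordered_set<uint64_t> tried;
    for (int so : seeds) {
      uint32_t key = 0;
      bool ok = true;
      for (int j = 0; j < K; ++j) {
        int b = twobit(rd[so + j]);
        if (b < 0) { ok = false; break; }
        key = (key << 2) | (uint32_t)b;
      }
      if (!ok) continue;
      auto it = st->idx.find(key);
      if (it == st->idx.end()) continue;
      for (uint64_t e : it->second) {
        int si = (int)(e >> 33);
        int strand = (int)(e & 1u);
        int pos = (int)((e >> 1) & 0xFFFFFFFFu);
        int a = pos - so;  // read start within oriented contig
        const std::string& c = strand ? st->rev[si] : st->fwd[si];
        if (a < 0 || a + n > (int)c.size()) continue;
        uint64_t tag = ((uint64_t)si << 33) | ((uint64_t)a << 1) |
                       (uint64_t)strand;
        if (tried.count(tag)) continue;
        tried.insert(tag);
        if (contigs.count(si)) continue;
        int mm = 0;
        bool pass = true;
        for (int j = 0; j < n; ++j) {
          if (!(PAT[(unsigned char)c[a + j]] & RD[(unsigned char)rd[j]])) {
            if ((int)qu[j] - 33 >= qmin && ++mm > max_mismatch) {
              pass = false;
              break;
            }
          }
        }
        if (pass) contigs.insert(si);
      }
    }
    for (int si : contigs) {
      o_read.push_back(ri + 1);
      o_contig.push_back(si + 1);
    }
  }
  return DataFrame::create(_["read"] = o_read, _["contig"] = o_contig,
                           _["stringsAsFactors"] = false);
}
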