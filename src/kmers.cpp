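// Low-level k-mer machinery: occurrence counting over sequence vectors and
// streaming queries of a fixed k-mer set. k <= 32 uses a rolling 2-bit
// encoding; longer k falls back to string keys. Windows containing any
// non-ACGT character are skipped in both paths.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline std::string decode_kmer(uint64_t code, int k) {
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = alpha[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// encode s[pos..pos+k); returns false if a non-ACGT base is hit
static inline bool encode_kmer(const char *s, int k, uint64_t &code) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

template <typename Fun>
static void scan_windows64(const char *s, int len, int k, Fun f) {
  // rolling scan; `valid` counts consecutive ACGT bases ending at i
  uint64_t code = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) {
      valid = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++valid >= k) f(code);
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 63) stop("k must be in [1, 63]");
  if (k <= 32) {
    std::unordered_map<uint64_t, double> tab;
    for (R_xlen_t r = 0; r < seqs.size(); ++r) {
      if (seqs[r] == NA_STRING) continue;
      const char *s = CHAR(seqs[r]);
      int len = (int)LENGTH(seqs[r]);
      scan_windows64(s, len, k, [&](uint64_t code) { tab[code] += 1.0; });
    }
    R_xlen_t n = (R_xlen_t)tab.size();
    CharacterVector kmers(n);
    NumericVector counts(n);
    R_xlen_t i = 0;
    for (auto &kv : tab) {
      kmers[i] = decode_kmer(kv.first, k);
      counts[i] = kv.second;
      ++i;
    }
    return List::create(_["kmer"] = kmers, _["count"] = counts);
  }
  std::unordered_map<std::string, double> tab;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    if (seqs[r] == NA_STRING) continue;
    const char *s = CHAR(seqs[r]);
    int len = (int)LENGTH(seqs[r]);
    for (int i = 0; i + k <= len; ++i) {
      bool ok = true;
      for (int j = 0; j < k; ++j)
        if (base2bits(s[i + j]) < 0) { ok = false; break; }
      if (!ok) continue;
      std::string km(s + i, s + i + k);
      for (auto &ch : km) ch = (char)toupper(ch);
      tab[km] += 1.0;
    }
  }
  R_xlen_t n = (R_xlen_t)tab.size();
  CharacterVector kmers(n);
  NumericVector counts(n);
  R_xlen_t i = 0;
  for (auto &kv : tab) {
    kmers[i] = kv.first;
    counts[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// Occurrences of each query k-mer over `seqs` (multiple hits per read all
// count). With both_strands, a window matching a query's reverse complement
// also counts toward that query. All queries must share one length <= 32.
// [[Rcpp::export]]
NumericVector cpp_stream_count(CharacterVector seqs, CharacterVector queries,
                               bool both_strands) {
  R_xlen_t nq = queries.size();
  NumericVector out(nq);
  if (nq == 0) return out;
  int k = (int)LENGTH(queries[0]);
  if (k < 1 || k > 32) stop("query k-mers must have length in [1, 32]");
  std::unordered_map<uint64_t, std::vector<int> > qmap;
  for (R_xlen_t i = 0; i < nq; ++i) {
    if ((int)LENGTH(queries[i]) != k) stop("query k-mers differ in length");
    uint64_t code;
    if (!encode_kmer(CHAR(queries[i]), k, code))
      stop("query k-mer contains non-ACGT characters");
    qmap[code].push_back((int)i);
    if (both_strands) {
      // reverse complement: complement is 3 - bits
      uint64_t rc = 0, c = code;
      for (int j = 0; j < k; ++j) {
        rc = (rc << 2) | (3ULL - (c & 3ULL));
        c >>= 2;
      }
      if (rc != code) qmap[rc].push_back((int)i);
    }
  }
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    if (seqs[r] == NA_STRING) continue;
    const char *s = CHAR(seqs[r]);
    int len = (int)LENGTH(seqs[r]);
    scan_windows64(s, len, k, [&](uint64_t code) {
      auto it = qmap.find(code);
      if (it != qmap.end())
        for (int qi : it->second) out[qi] += 1.0;
    });
  }
  return out;
}
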