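// Unitig assembly of a DE k-mer set: contigs are maximal non-branching paths
// in the graph linking k-mers whose (k-1)-suffix equals another's (k-1)-prefix.
// Extension stops at branches; every input k-mer ends up in exactly one
// contig. Self-loops and cycles are broken deterministically (walk starts at
// the lowest input index on the cycle).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

static const char ALPHA[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
List cpp_assemble_unitigs(CharacterVector kmers, int k) {
  int n = (int)kmers.size();
  std::unordered_map<std::string, int> idx;
  std::vector<std::string> km(n);
  for (int i = 0; i < n; ++i) {
    km[i] = std::string(CHAR(kmers[i]));
    if ((int)km[i].size() != k) stop("k-mer length differs from k");
    if (!idx.emplace(km[i], i).second) stop("duplicate k-mers in input");
  }

  // unique successor / predecessor (-1 = none or ambiguous)
  std::vector<int> us(n, -1), up(n, -1);
  for (int i = 0; i < n; ++i) {
    std::string suf = km[i].substr(1);
    int succ = -1, nsucc = 0;
    std::string cand = suf + "A";
    for (int b = 0; b < 4; ++b) {
      cand[k - 1] = ALPHA[b];
      auto it = idx.find(cand);
      if (it != idx.end()) { succ = it->second; ++nsucc; }
    }
    us[i] = (nsucc == 1) ? succ : -1;

    std::string pre = km[i].substr(0, k - 1);
    int pred = -1, npred = 0;
    std::string candp = "A" + pre;
    for (int b = 0; b < 4; ++b) {
      candp[0] = ALPHA[b];
      auto it = idx.find(candp);
      if (it != idx.end()) { pred = it->second; ++npred; }
    }
    up[i] = (npred == 1) ? pred : -1;
  }

  // keep edge i -> us[i] only when mutually unique
  std::vector<int> nxt(n, -1), prv(n, -1);
  for (int i = 0; i < n; ++i) {
    int j = us[i];
    if (j >= 0 && up[j] == i && j != i) { nxt[i] = j; prv[j] = i; }
  }

  std::vector<char> used(n, 0);
  std::vector<std::string> contigs;
  std::vector<std::vector<int> > members;

  auto walk = [&](int start) {
    std::string seq = km[start];
    std::vector<int> mem;
    mem.push_back(start + 1); // 1-based
    used[start] = 1;
    int cur = start;
    while (nxt[cur] >= 0 && !used[nxt[cur]]) {
      cur = nxt[cur];
      used[cur] = 1;
      seq.push_back(km[cur][k - 1]);
      mem.push_back(cur + 1);
    }
    contigs.push_back(seq);
    members.push_back(mem);
  };

  for (int i = 0; i < n; ++i)
    if (!used[i] && prv[i] < 0) walk(i); // chain starts
  for (int i = 0; i < n; ++i)
    if (!used[i]) walk(i); // remaining nodes sit on cycles; break at lowest index

  R_xlen_t m = (R_xlen_t)contigs.size();
  CharacterVector cseq(m);
  List cmem(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    cseq[i] = contigs[i];
    cmem[i] = wrap(members[i]);
  }
  return List::create(_["sequence"] = cseq, _["members"] = cmem);
}
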