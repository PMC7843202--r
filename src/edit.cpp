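#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Units are integer ids (character codes or word-table indices); the same DP
// serves both character-level and word-level alignment.

static inline int lev_core(const int* a, int n, const int* b, int m,
                           std::vector<int>* tab) {
  // full (n+1) x (m+1) table kept only when a traceback is requested
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  if (tab) std::copy(prev.begin(), prev.end(), tab->begin());
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int best = sub < del ? sub : del;
      cur[j] = best < ins ? best : ins;
    }
    if (tab) std::copy(cur.begin(), cur.end(), tab->begin() + (size_t)i * (m + 1));
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int C_lev_dist(IntegerVector a, IntegerVector b) {
  return lev_core(a.begin(), a.size(), b.begin(), b.size(), nullptr);
}

// Canonical minimal alignment of a into b. Ties during backtrace are broken
// by preferring the diagonal move (SAME/SUBSTITUTE), then the vertical move
// (DELETE), then the horizontal move (INSERT), so extraction is
// deterministic. Returns a matrix with columns kind (0 SAME, 1 INSERT,
// 2 DELETE, 3 SUBSTITUTE), source id (NA for INSERT), target id (NA for
// DELETE); SAME rows carry the unit in both columns.
// [[Rcpp::export]]
IntegerMatrix C_lev_align(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  std::vector<int> tab((size_t)(n + 1) * (m + 1));
  lev_core(a.begin(), n, b.begin(), m, &tab);
  std::vector<int> kind, src, tgt;
  int i = n, j = m;
  const int W = m + 1;
  while (i > 0 || j > 0) {
    int here = tab[(size_t)i * W + j];
    if (i > 0 && j > 0) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      if (tab[(size_t)(i - 1) * W + (j - 1)] + cost == here) {
        kind.push_back(cost == 0 ? 0 : 3);
        src.push_back(a[i - 1]);
        tgt.push_back(b[j - 1]);
        --i; --j;
        continue;
      }
    }
    if (i > 0 && tab[(size_t)(i - 1) * W + j] + 1 == here) {
      kind.push_back(2); src.push_back(a[i - 1]); tgt.push_back(NA_INTEGER);
      --i;
      continue;
    }
    kind.push_back(1); src.push_back(NA_INTEGER); tgt.push_back(b[j - 1]);
    --j;
  }
  int k = kind.size();
  IntegerMatrix out(k, 3);
  for (int r = 0; r < k; ++r) {  // backtrace built the ops in reverse
    out(r, 0) = kind[k - 1 - r];
    out(r, 1) = src[k - 1 - r];
    out(r, 2) = tgt[k - 1 - r];
  }
  colnames(out) = CharacterVector::create("kind", "source", "target");
  return out;
}

// All pairwise byte-level distances between two string vectors; used by the
// exhaustive small-alphabet equivalence checks where per-call overhead from
// R would dominate.
// [[Rcpp::export]]
IntegerMatrix C_lev_dist_matrix(CharacterVector s, CharacterVector t) {
  int ns = s.size(), nt = t.size();
  std::vector<std::vector<int>> sv(ns), tv(nt);
  for (int i = 0; i < ns; ++i) {
    const char* p = CHAR(STRING_ELT(s, i));
    for (; *p; ++p) sv[i].push_back((unsigned char)*p);
  }
  for (int j = 0; j < nt; ++j) {
    const char* p = CHAR(STRING_ELT(t, j));
    for (; *p; ++p) tv[j].push_back((unsigned char)*p);
  }
  IntegerMatrix out(ns, nt);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < nt; ++j)
      out(i, j) = lev_core(sv[i].data(), sv[i].size(), tv[j].data(), tv[j].size(), nullptr);
  return out;
}
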