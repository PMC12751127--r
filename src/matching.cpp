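#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Character equality under the ambiguity rule used throughout the package:
// 'N' never matches any base, including another 'N'.
static inline bool base_eq(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

static int hamming(const char* a, const char* b, int n) {
  int d = 0;
  for (int i = 0; i < n; ++i)
    if (!base_eq(a[i], b[i])) ++d;
  return d;
}

// Full Levenshtein DP with unit costs; substitution is free only when
// base_eq holds, so N incurs an edit against everything.
static int levenshtein(const char* a, int na, const char* b, int nb) {
  std::vector<int> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (base_eq(a[i - 1], b[j - 1]) ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export(name = ".hamming_distance_cpp")]]
int hamming_distance_cpp(std::string a, std::string b) {
  if (a.size() != b.size())
    stop("hamming distance requires equal-length sequences (%d vs %d)",
         (int)a.size(), (int)b.size());
  return hamming(a.c_str(), b.c_str(), (int)a.size());
}

// [[Rcpp::export(name = ".levenshtein_distance_cpp")]]
int levenshtein_distance_cpp(std::string a, std::string b) {
  return levenshtein(a.c_str(), (int)a.size(), b.c_str(), (int)b.size());
}

// Batch match of seqs against refs by Hamming distance with cutoff max_mm.
// A query whose length differs from a reference's length cannot hit it;
// n_hits counts every reference within the cutoff, hit_index is the 1-based
// index of the single hit when n_hits == 1 and NA otherwise.
// [[Rcpp::export(name = ".match_hamming_cpp")]]
List match_hamming_cpp(CharacterVector seqs, CharacterVector refs, int max_mm) {
  int n = seqs.size(), m = refs.size();
  std::vector<const char*> rp(m);
  std::vector<int> rl(m);
  for (int k = 0; k < m; ++k) {
    rp[k] = CHAR(STRING_ELT(refs, k));
    rl[k] = (int)std::strlen(rp[k]);
  }
  IntegerVector n_hits(n), hit_index(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int sl = (int)std::strlen(s);
    int hits = 0, idx = NA_INTEGER;
    for (int k = 0; k < m; ++k) {
      if (rl[k] != sl) continue;
      if (hamming(s, rp[k], sl) <= max_mm) {
        if (++hits == 1) idx = k + 1;
      }
    }
    n_hits[i] = hits;
    hit_index[i] = (hits == 1) ? idx : NA_INTEGER;
  }
  return List::create(_["n_hits"] = n_hits, _["hit_index"] = hit_index);
}

// Batch match by normalized edit-distance similarity
// 1 - levenshtein(q, ref) / nchar(ref), floored at 0, cutoff min_ratio.
// [[Rcpp::export(name = ".match_ratio_cpp")]]
List match_ratio_cpp(CharacterVector seqs, CharacterVector refs,
                     double min_ratio) {
  int n = seqs.size(), m = refs.size();
  std::vector<const char*> rp(m);
  std::vector<int> rl(m);
  for (int k = 0; k < m; ++k) {
    rp[k] = CHAR(STRING_ELT(refs, k));
    rl[k] = (int)std::strlen(rp[k]);
    if (rl[k] == 0) stop("empty reference sequence at position %d", k + 1);
  }
  IntegerVector n_hits(n), hit_index(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int sl = (int)std::strlen(s);
    int hits = 0, idx = NA_INTEGER;
    for (int k = 0; k < m; ++k) {
      double sim = 1.0 - (double)levenshtein(s, sl, rp[k], rl[k]) / rl[k];
      if (sim < 0) sim = 0;
      if (sim >= min_ratio) {
        if (++hits == 1) idx = k + 1;
      }
    }
    n_hits[i] = hits;
    hit_index[i] = (hits == 1) ? idx : NA_INTEGER;
  }
  return List::create(_["n_hits"] = n_hits, _["hit_index"] = hit_index);
}

// Edge list (1-based pairs) over distinct UMIs with Hamming distance <=
// max_mm; used by fuzzy UMI deduplication to build connected components.
// [[Rcpp::export(name = ".umi_edges_cpp")]]
IntegerMatrix umi_edges_cpp(CharacterVector umis, int max_mm) {
  int n = umis.size();
  std::vector<const char*> up(n);
  std::vector<int> ul(n);
  for (int i = 0; i < n; ++i) {
    up[i] = CHAR(STRING_ELT(umis, i));
    ul[i] = (int)std::strlen(up[i]);
  }
  std::vector<int> from, to;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (ul[i] != ul[j]) continue;
      if (hamming(up[i], up[j], ul[i]) <= max_mm) {
        from.push_back(i + 1);
        to.push_back(j + 1);
      }
    }
  IntegerMatrix out((int)from.size(), 2);
  for (size_t e = 0; e < from.size(); ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return out;
}
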