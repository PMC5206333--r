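#include <Rcpp.h>
#include <array>
#include <functional>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bruvo genotype distances for tetraploids.
// Per-allele distance d = 1 - 2^(-|x|) with x the repeat-count difference;
// genotype distance = min over bijective assignments of the mean d;
// dosage-ambiguous genotypes (1-3 distinct repeat counts) are expanded to
// every completion to 4 copies and the mean over completion pairs returned
// (genome-addition-style averaging).

static const int PERMS4[24][4] = {
  {0,1,2,3},{0,1,3,2},{0,2,1,3},{0,2,3,1},{0,3,1,2},{0,3,2,1},
  {1,0,2,3},{1,0,3,2},{1,2,0,3},{1,2,3,0},{1,3,0,2},{1,3,2,0},
  {2,0,1,3},{2,0,3,1},{2,1,0,3},{2,1,3,0},{2,3,0,1},{2,3,1,0},
  {3,0,1,2},{3,0,2,1},{3,1,0,2},{3,1,2,0},{3,2,0,1},{3,2,1,0}};

static void completions(const std::vector<int>& a,
                        std::vector<std::array<int,4>>& out) {
  int k = a.size();
  out.clear();
  std::array<int,4> g;
  if (k == 4) {
    for (int i = 0; i < 4; ++i) g[i] = a[i];
    out.push_back(g);
    return;
  }
  int extra = 4 - k;
  // compositions of `extra` over k slots
  std::vector<int> comp(k, 0);
  std::function<void(int,int)> rec = [&](int pos, int left) {
    if (pos == k - 1) {
      comp[pos] = left;
      int idx = 0;
      for (int i = 0; i < k; ++i)
        for (int c = 0; c <= comp[i]; ++c) g[idx++] = a[i];
      out.push_back(g);
      return;
    }
    for (int i = 0; i <= left; ++i) { comp[pos] = i; rec(pos + 1, left - i); }
  };
  rec(0, extra);
}

static double assignMin(const std::array<int,4>& a, const std::array<int,4>& b) {
  double best = R_PosInf;
  for (int p = 0; p < 24; ++p) {
    double s = 0.0;
    for (int i = 0; i < 4; ++i) {
      int x = a[i] - b[PERMS4[p][i]];
      if (x < 0) x = -x;
      s += 1.0 - std::pow(2.0, -(double)x);
    }
    if (s < best) best = s;
  }
  return best / 4.0;
}

// [[Rcpp::export]]
double bruvo_locus_cpp(IntegerVector a, IntegerVector b) {
  if (a.size() == 0 || b.size() == 0) return NA_REAL;
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<std::array<int,4>> ca, cb;
  completions(av, ca);
  completions(bv, cb);
  double acc = 0.0;
  for (size_t i = 0; i < ca.size(); ++i)
    for (size_t j = 0; j < cb.size(); ++j)
      acc += assignMin(ca[i], cb[j]);
  return acc / (double)(ca.size() * cb.size());
}

// cells: list of length n*L (column-major: individual i, locus l at
// index l*n + i) of integer repeat-count vectors (length 0 = missing)
// [[Rcpp::export]]
List bruvo_matrix_cpp(List cells, int n, int L) {
  NumericMatrix D(n, n);
  IntegerMatrix shared(n, n);
  // precompute completions per cell
  std::vector<std::vector<std::array<int,4>>> comp(n * L);
  for (int idx = 0; idx < n * L; ++idx) {
    IntegerVector v = cells[idx];
    if (v.size() > 0) {
      std::vector<int> vv(v.begin(), v.end());
      completions(vv, comp[idx]);
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double acc = 0.0; int ns = 0;
      for (int l = 0; l < L; ++l) {
        const auto& ca = comp[l * n + i];
        const auto& cb = comp[l * n + j];
        if (ca.empty() || cb.empty()) continue;
        double s = 0.0;
        for (size_t u = 0; u < ca.size(); ++u)
          for (size_t v2 = 0; v2 < cb.size(); ++v2)
            s += assignMin(ca[u], cb[v2]);
        acc += s / (double)(ca.size() * cb.size());
        ++ns;
      }
      shared(i, j) = shared(j, i) = ns;
      D(i, j) = D(j, i) = (ns > 0) ? acc / ns : NA_REAL;
    }
  }
  return List::create(_["d"] = D, _["shared"] = shared);
}
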