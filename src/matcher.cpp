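#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Seed-and-extend pairwise IBD matcher over a phased 0/1 allele matrix.
//
// Markers are partitioned into consecutive words of `bits` markers with
// fixed boundaries (marker index / bits). Haplotypes sharing the value of a
// word are candidate pairs; a candidate is seeded only at the *first*
// matching word of a run (the previous word differs), the match is extended
// word-by-word and then marker-by-marker at both flanks, and maximal
// segments of genetic length >= min_m cM are reported once per pair.
//
// With err_hom == 0 this reproduces exactly the maximal identical runs that
// contain at least one fully aligned word. err_hom > 0 extends under a
// shared mismatch budget and trims trailing mismatches (best effort).

static inline std::vector<uint32_t> pack_words(const IntegerMatrix &a,
                                               int h, int bits, int W) {
  const int M = a.ncol();
  std::vector<uint32_t> w(W);
  for (int k = 0; k < W; ++k) {
    uint32_t v = 0;
    const int lo = k * bits;
    const int hi = std::min(M, lo + bits);
    for (int i = lo; i < hi; ++i) v = (v << 1) | (uint32_t)a(h, i);
    w[k] = v;
  }
  return w;
}

// [[Rcpp::export(name = ".ibd_match_cpp")]]
DataFrame ibd_match_cpp(const IntegerMatrix &alleles,
                        const NumericVector &cM,
                        int bits, double min_m, int err_hom) {
  const int H = alleles.nrow();
  const int M = alleles.ncol();
  if (H < 2 || M == 0)
    return DataFrame::create(_["hap1"] = IntegerVector(0),
                             _["hap2"] = IntegerVector(0),
                             _["start"] = IntegerVector(0),
                             _["end"] = IntegerVector(0));
  if (bits < 1 || bits > 31) stop("bits must be in [1, 31]");
  const int W = (M + bits - 1) / bits;

  std::vector<std::vector<uint32_t> > words(H);
  for (int h = 0; h < H; ++h) words[h] = pack_words(alleles, h, bits, W);

  std::vector<int> oi, oj, os, oe;
  std::set<std::tuple<int, int, int, int> > seen; // err_hom > 0 dedupe

  std::vector<std::pair<uint32_t, int> > bucket(H);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) bucket[h] = std::make_pair(words[h][w], h);
    std::sort(bucket.begin(), bucket.end());
    int g0 = 0;
    while (g0 < H) {
      int g1 = g0;
      while (g1 + 1 < H && bucket[g1 + 1].first == bucket[g0].first) ++g1;
      for (int x = g0; x <= g1; ++x) {
        for (int y = x + 1; y <= g1; ++y) {
          const int i = std::min(bucket[x].second, bucket[y].second);
          const int j = std::max(bucket[x].second, bucket[y].second);
          if (w > 0 && words[i][w - 1] == words[j][w - 1])
            continue; // this run was seeded at an earlier word
          // extend over consecutive identical words
          int w2 = w;
          while (w2 + 1 < W && words[i][w2 + 1] == words[j][w2 + 1]) ++w2;
          int s = w * bits;
          int e = std::min(M - 1, (w2 + 1) * bits - 1);
          if (err_hom == 0) {
            // flank extension cannot cross the mismatching words adjacent
            // to the run; skip when even the widest reach stays < min_m
            const int smin = (w > 0) ? (w - 1) * bits : 0;
            const int emax = std::min(M - 1, (w2 + 2) * bits - 1);
            if (cM[emax] - cM[smin] < min_m) continue;
            while (s > 0 && alleles(i, s - 1) == alleles(j, s - 1)) --s;
            while (e + 1 < M && alleles(i, e + 1) == alleles(j, e + 1)) ++e;
            if (cM[e] - cM[s] >= min_m) {
              oi.push_back(i); oj.push_back(j);
              os.push_back(s); oe.push_back(e);
            }
          } else {
            // mismatch-tolerant: shared budget, right first, trim trailing
            int used = 0, p = e, last_match = e;
            while (p + 1 < M) {
              ++p;
              if (alleles(i, p) == alleles(j, p)) { last_match = p; }
              else if (++used > err_hom) { --used; break; }
            }
            e = last_match;
            p = s; last_match = s;
            while (p > 0) {
              --p;
              if (alleles(i, p) == alleles(j, p)) { last_match = p; }
              else if (++used > err_hom) { --used; break; }
            }
            s = last_match;
            if (cM[e] - cM[s] >= min_m &&
                seen.insert(std::make_tuple(i, j, s, e)).second) {
              oi.push_back(i); oj.push_back(j);
              os.push_back(s); oe.push_back(e);
            }
          }
        }
      }
      g0 = g1 + 1;
    }
  }

  const int n = (int)oi.size();
  IntegerVector ri(n), rj(n), rs(n), re(n);
  for (int k = 0; k < n; ++k) {
    ri[k] = oi[k] + 1; rj[k] = oj[k] + 1;
    rs[k] = os[k] + 1; re[k] = oe[k] + 1;
  }
  return DataFrame::create(_["hap1"] = ri, _["hap2"] = rj,
                           _["start"] = rs, _["end"] = re);
}

// Connected components of per-window sharing graphs.
//
// Edges (h1, h2) are grouped by window id (`win` must be sorted
// ascending); for each window a union-find over the incident haplotypes is
// run and one row (win, hap, root) per incident haplotype is returned.

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}

// [[Rcpp::export(name = ".window_components_cpp")]]
DataFrame window_components_cpp(const IntegerVector &win,
                                const IntegerVector &h1,
                                const IntegerVector &h2,
                                int n_haps) {
  const int n = win.size();
  std::vector<int> parent(n_haps + 1), stamp(n_haps + 1, -1);
  std::vector<int> ow, oh, oroot;
  int k = 0;
  while (k < n) {
    const int w = win[k];
    int k2 = k;
    while (k2 + 1 < n && win[k2 + 1] == w) ++k2;
    std::vector<int> touched;
    for (int t = k; t <= k2; ++t) {
      for (int hh : {(int)h1[t], (int)h2[t]}) {
        if (stamp[hh] != w) { stamp[hh] = w; parent[hh] = hh;
                              touched.push_back(hh); }
      }
      int a = uf_find(parent, h1[t]), b = uf_find(parent, h2[t]);
      if (a != b) parent[b] = a;
    }
    std::sort(touched.begin(), touched.end());
    for (int hh : touched) {
      ow.push_back(w); oh.push_back(hh);
      oroot.push_back(uf_find(parent, hh));
    }
    k = k2 + 1;
  }
  return DataFrame::create(_["win"] = IntegerVector(ow.begin(), ow.end()),
                           _["hap"] = IntegerVector(oh.begin(), oh.end()),
                           _["root"] = IntegerVector(oroot.begin(),
                                                     oroot.end()));
}
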