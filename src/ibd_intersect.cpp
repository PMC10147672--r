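#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Pairwise matched-interval extraction for the true-IBD engine.
//
// Input: one row per mosaic segment, sorted by (chrom, fid, start):
//   hap   global haplotype index (1-based, two per individual)
//   chrom integer chromosome index
//   fid   founder-haplotype label
//   start,end cM coordinates
// For every pair of haplotypes carrying the same fid on the same chromosome
// the overlap interval is collected; overlaps of one haplotype pair that
// touch (the founder label may change across the junction) are then merged
// into maximal matched intervals.
//
// Returns a list of vectors (hap1, hap2, chrom, start, end) with hap1 < hap2.

// [[Rcpp::export]]
List ibd_intersect_cpp(IntegerVector hap, IntegerVector chrom,
                       IntegerVector fid, NumericVector start,
                       NumericVector end, bool within_only,
                       bool cross_only) {
  const R_xlen_t n = hap.size();
  std::vector<int> h1, h2, ch;
  std::vector<double> s, e;
  h1.reserve(1024); h2.reserve(1024); ch.reserve(1024);
  s.reserve(1024); e.reserve(1024);

  R_xlen_t g0 = 0;
  while (g0 < n) {
    R_xlen_t g1 = g0 + 1;
    while (g1 < n && chrom[g1] == chrom[g0] && fid[g1] == fid[g0]) ++g1;
    for (R_xlen_t i = g0; i < g1; ++i) {
      for (R_xlen_t j = i + 1; j < g1; ++j) {
        if (hap[i] == hap[j]) continue;
        double ss = std::max(start[i], start[j]);
        double ee = std::min(end[i], end[j]);
        if (ee - ss <= 1e-12) continue;
        int a = hap[i], b = hap[j];
        if (a > b) std::swap(a, b);
        int ia = (a - 1) / 2, ib = (b - 1) / 2;
        if (within_only && ia != ib) continue;
        if (cross_only && ia == ib) continue;
        h1.push_back(a); h2.push_back(b); ch.push_back(chrom[i]);
        s.push_back(ss); e.push_back(ee);
      }
    }
    g0 = g1;
  }

  const size_t m = h1.size();
  std::vector<size_t> ord(m);
  for (size_t k = 0; k < m; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (h1[a] != h1[b]) return h1[a] < h1[b];
    if (h2[a] != h2[b]) return h2[a] < h2[b];
    if (ch[a] != ch[b]) return ch[a] < ch[b];
    return s[a] < s[b];
  });

  std::vector<int> oh1, oh2, och;
  std::vector<double> os, oe;
  for (size_t k = 0; k < m; ++k) {
    size_t idx = ord[k];
    bool same = !os.empty() && oh1.back() == h1[idx] &&
      oh2.back() == h2[idx] && och.back() == ch[idx] &&
      s[idx] <= oe.back() + 1e-9;
    if (same) {
      if (e[idx] > oe.back()) oe.back() = e[idx];
    } else {
      oh1.push_back(h1[idx]); oh2.push_back(h2[idx]);
      och.push_back(ch[idx]); os.push_back(s[idx]); oe.push_back(e[idx]);
    }
  }

  return List::create(_["hap1"] = wrap(oh1), _["hap2"] = wrap(oh2),
                      _["chrom"] = wrap(och), _["start"] = wrap(os),
                      _["end"] = wrap(oe));
}
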