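#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// EHH bookkeeping via haplotype bitsets. A "group" is the set of haplotypes
// identical over every marker seen so far (strictly between the core and
// the current marker, current marker included). Groups are W-word bitmasks;
// singleton groups are dropped because they can never contribute a pair.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

struct BitPanel {
  int H, W;
  std::vector<uint64_t> site_mask;   // S x W: alt-allele mask per site
  std::vector<uint64_t> full;        // W: mask of all haplotypes
};

static BitPanel build_panel(const IntegerMatrix& hap) {
  BitPanel p;
  p.H = hap.ncol();
  p.W = (p.H + 63) / 64;
  const int S = hap.nrow();
  p.site_mask.assign((size_t)S * p.W, 0ULL);
  for (int s = 0; s < S; ++s) {
    uint64_t* row = &p.site_mask[(size_t)s * p.W];
    for (int h = 0; h < p.H; ++h) {
      if (hap(s, h) != 0) row[h >> 6] |= (1ULL << (h & 63));
    }
  }
  p.full.assign(p.W, 0ULL);
  for (int h = 0; h < p.H; ++h) p.full[h >> 6] |= (1ULL << (h & 63));
  return p;
}

// integral of EHH over physical distance on one side of the core
static double ihh_one_side(const BitPanel& p, const NumericVector& pos,
                           int lo, int hi, int core, int dir,
                           double min_ehh, double max_extend) {
  const double pairs_all = 0.5 * (double)p.H * (p.H - 1);
  if (pairs_all <= 0) return 0.0;
  const int W = p.W;
  std::vector<uint64_t> groups(p.full);        // start: one group, all haps
  std::vector<uint64_t> next; next.reserve(16 * W);
  double ehh_prev = 1.0, dist_prev = 0.0, ihh = 0.0;
  for (int s = core + dir; s >= lo && s <= hi; s += dir) {
    double dist = std::abs(pos[s] - pos[core]);
    if (dist > max_extend) break;
    const uint64_t* m = &p.site_mask[(size_t)s * W];
    next.clear();
    double sum_pairs = 0.0;
    for (size_t g = 0; g < groups.size(); g += W) {
      int c1 = 0, c0 = 0;
      for (int w = 0; w < W; ++w) {
        c1 += popcount64(groups[g + w] & m[w]);
        c0 += popcount64(groups[g + w] & ~m[w]);
      }
      if (c1 >= 2) {
        sum_pairs += 0.5 * (double)c1 * (c1 - 1);
        for (int w = 0; w < W; ++w) next.push_back(groups[g + w] & m[w]);
      }
      if (c0 >= 2) {
        sum_pairs += 0.5 * (double)c0 * (c0 - 1);
        for (int w = 0; w < W; ++w) next.push_back(groups[g + w] & ~m[w]);
      }
    }
    double ehh = sum_pairs / pairs_all;
    ihh += 0.5 * (ehh_prev + ehh) * (dist - dist_prev);
    ehh_prev = ehh; dist_prev = dist;
    if (ehh < min_ehh) break;
    groups.swap(next);
    if (groups.empty()) break;                 // EHH is 0 from here on
  }
  return ihh;
}

// [[Rcpp::export(name = ".ihh_scan_cpp")]]
NumericVector ihh_scan_cpp(IntegerMatrix hap, NumericVector pos,
                           IntegerVector chrom_id, double min_ehh,
                           double max_extend) {
  const int S = hap.nrow();
  BitPanel p = build_panel(hap);
  NumericVector out(S);
  int block_start = 0;
  for (int s = 0; s < S; ++s) {
    if (s + 1 == S || chrom_id[s + 1] != chrom_id[s]) {
      for (int core = block_start; core <= s; ++core) {
        out[core] =
          ihh_one_side(p, pos, block_start, s, core, -1, min_ehh, max_extend) +
          ihh_one_side(p, pos, block_start, s, core, +1, min_ehh, max_extend);
      }
      block_start = s + 1;
    }
  }
  return out;
}
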