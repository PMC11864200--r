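#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Constant-weight binary codes are held as matrices of on-bit positions
// (rows = words, w columns, 1-based bit index, bit 1 = MSB of the printed
// barcode). For two words of equal weight w, Hamming distance
// HD = 2 * (w - shared on-bits), so HD >= min_hd  <=>  shared <= w - min_hd/2.
// Bit masks (up to 128 bits) make the shared-count a pair of popcounts.

namespace {

struct Mask {
  uint64_t lo, hi;
};

inline Mask make_mask(const IntegerMatrix &pos, int row) {
  Mask m = {0, 0};
  for (int j = 0; j < pos.ncol(); ++j) {
    int b = pos(row, j) - 1;
    if (b < 64) m.lo |= (uint64_t)1 << b; else m.hi |= (uint64_t)1 << (b - 64);
  }
  return m;
}

inline int shared(const Mask &a, const Mask &b) {
  return __builtin_popcountll(a.lo & b.lo) + __builtin_popcountll(a.hi & b.hi);
}

inline int hd(const Mask &a, const Mask &b) {
  return __builtin_popcountll(a.lo ^ b.lo) + __builtin_popcountll(a.hi ^ b.hi);
}

}  // namespace

// Greedy scan in the given candidate order: accept a word iff it shares at
// most `max_shared` on-bits with every accepted word. Returns 1-based row
// indices (into `pos`) of the accepted words, in acceptance order.
// [[Rcpp::export(name = ".cw_greedy")]]
IntegerVector cw_greedy(IntegerMatrix pos, IntegerVector order, int max_shared) {
  std::vector<Mask> acc;
  std::vector<int> idx;
  const int n = order.size();
  for (int k = 0; k < n; ++k) {
    int row = order[k] - 1;
    Mask m = make_mask(pos, row);
    bool ok = true;
    for (size_t j = 0; j < acc.size(); ++j)
      if (shared(acc[j], m) > max_shared) { ok = false; break; }
    if (ok) {
      acc.push_back(m);
      idx.push_back(row + 1);
    }
  }
  return wrap(idx);
}

// Exhaustive pairwise check; returns the minimum pairwise Hamming distance.
// [[Rcpp::export(name = ".cw_min_hd")]]
int cw_min_hd(IntegerMatrix pos, int n_bits) {
  const int n = pos.nrow();
  if (n < 2) return 2 * n_bits;
  std::vector<Mask> m(n);
  for (int i = 0; i < n; ++i) m[i] = make_mask(pos, i);
  int best = 2 * n_bits;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = hd(m[i], m[j]);
      if (d < best) best = d;
    }
  return best;
}

// Decode readout bit vectors against a code: exact match, else a unique
// codeword at Hamming distance 1 (single-error correction), else 0.
// `queries` is n_q x n_bits of 0/1. Returns 1-based codeword index or 0.
// [[Rcpp::export(name = ".cw_decode")]]
IntegerVector cw_decode(IntegerMatrix queries, IntegerMatrix pos) {
  const int nq = queries.nrow(), nb = queries.ncol(), nc = pos.nrow();
  std::vector<Mask> code(nc);
  for (int i = 0; i < nc; ++i) code[i] = make_mask(pos, i);
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    Mask m = {0, 0};
    for (int b = 0; b < nb; ++b)
      if (queries(q, b)) {
        if (b < 64) m.lo |= (uint64_t)1 << b; else m.hi |= (uint64_t)1 << (b - 64);
      }
    int exact = 0, near = 0, n_near = 0;
    for (int i = 0; i < nc; ++i) {
      int d = hd(m, code[i]);
      if (d == 0) { exact = i + 1; break; }
      if (d == 1) { near = i + 1; ++n_near; }
    }
    out[q] = exact ? exact : (n_near == 1 ? near : 0);
  }
  return out;
}

// Greedy balanced barcode assignment. Loci are processed in input order and
// must be grouped by chromosome (`chrom` = integer chromosome id per locus).
// Candidate words are scanned in the order of `cand` (seed-shuffled upstream);
// the chosen word minimizes, lexicographically: (max per-chromosome per-bit
// load after assignment, max global per-bit load after assignment, sum of
// global loads over the word's bits), ties broken by candidate order.
// Returns a 1-based row index into `pos` per locus.
// [[Rcpp::export(name = ".cw_balance_assign")]]
IntegerVector cw_balance_assign(IntegerMatrix pos, int n_bits,
                                IntegerVector cand, IntegerVector chrom) {
  const int n_loci = chrom.size(), w = pos.ncol(), ncand = cand.size();
  int n_chrom = 0;
  for (int i = 0; i < n_loci; ++i) n_chrom = std::max(n_chrom, chrom[i]);
  std::vector<int> gload(n_bits, 0);
  std::vector<std::vector<int>> cload(n_chrom, std::vector<int>(n_bits, 0));
  std::vector<char> used(pos.nrow(), 0);
  IntegerVector out(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    int ch = chrom[l] - 1;
    int best = -1, b_cm = INT_MAX, b_gm = INT_MAX, b_gs = INT_MAX;
    for (int k = 0; k < ncand; ++k) {
      int row = cand[k] - 1;
      if (used[row]) continue;
      int cm = 0, gm = 0, gs = 0;
      for (int j = 0; j < w; ++j) {
        int b = pos(row, j) - 1;
        cm = std::max(cm, cload[ch][b] + 1);
        gm = std::max(gm, gload[b] + 1);
        gs += gload[b];
      }
      if (cm < b_cm || (cm == b_cm && (gm < b_gm || (gm == b_gm && gs < b_gs)))) {
        b_cm = cm; b_gm = gm; b_gs = gs; best = row;
      }
    }
    if (best < 0) stop("fewer unused codewords than loci");
    used[best] = 1;
    out[l] = best + 1;
    for (int j = 0; j < w; ++j) {
      int b = pos(best, j) - 1;
      ++gload[b];
      ++cload[ch][b];
    }
  }
  return out;
}
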