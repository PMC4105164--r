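#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Seed-and-extend scan for approximate repeated segments between two strings.
//
// A "window" is a run of aligned positions a[ia+t] == b[ib+t] (t = 0..len-1)
// along one diagonal d = ib - ia, containing at most max_mm mismatching
// positions, and maximal: it cannot be extended on either side without
// either adding a mismatch beyond the budget or leaving the sequence.
// Completeness: every window of length >= min_len with <= max_mm mismatches
// contains an exact run of >= ceil((min_len - max_mm)/(max_mm + 1))
// positions (pigeonhole), so seeding at that length misses nothing.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N and friends never seed, never match
  }
}

// [[Rcpp::export]]
DataFrame cpp_diag_windows(std::string a, std::string b,
                           int min_len, int max_mm, int seed_len,
                           bool self_mode) {
  const long na = (long)a.size(), nb = (long)b.size();
  std::vector<int> ca(na), cb(nb);
  for (long i = 0; i < na; ++i) ca[i] = base_code(a[i]);
  for (long i = 0; i < nb; ++i) cb[i] = base_code(b[i]);

  std::vector<long> out_ia, out_ib, out_len;
  std::vector<int> out_mm;
  if (na < seed_len || nb < seed_len || seed_len < 1 || seed_len > 31)
    return DataFrame::create(_["ia"] = out_ia, _["ib"] = out_ib,
                             _["len"] = out_len, _["mm"] = out_mm);

  // index all seed_len-mers of b
  std::unordered_map<uint64_t, std::vector<long> > idx;
  idx.reserve((size_t)nb * 2);
  {
    uint64_t key = 0, mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
    int valid = 0;
    for (long i = 0; i < nb; ++i) {
      int c = cb[i];
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= seed_len) idx[key].push_back(i - seed_len + 1);
    }
  }

  // per-diagonal: rightmost position (in a-coordinates) of a seed gap
  // already enumerated, so each exact run is processed once
  std::unordered_map<long, long> gap_done;
  std::unordered_set<uint64_t> seen;  // packed (diag, start, end)

  uint64_t key = 0, mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  int valid = 0;
  for (long i = 0; i < na; ++i) {
    int c = ca[i];
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid < seed_len) continue;
    long sa = i - seed_len + 1; // seed start in a
    std::unordered_map<uint64_t, std::vector<long> >::iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<long>& hits = it->second;
    for (size_t h = 0; h < hits.size(); ++h) {
      long sb = hits[h];
      long d = sb - sa;
      if (self_mode && d <= 0) continue; // self comparison: upper diagonals only
      // overlap range of this diagonal in a-coordinates
      long lo = (d >= 0) ? 0 : -d;           // first a-pos on diagonal
      long hi = (d >= 0) ? std::min(na - 1, nb - 1 - d) : (na - 1);
      hi = std::min(hi, nb - 1 - d);
      std::unordered_map<long, long>::iterator gd = gap_done.find(d);
      if (gd != gap_done.end() && sa + seed_len - 1 <= gd->second) continue;

      // expand seed to its full exact run (gap between mismatches)
      long gs = sa, ge = sa + seed_len - 1;
      while (gs - 1 >= lo && ca[gs - 1] >= 0 && cb[gs - 1 + d] >= 0 &&
             ca[gs - 1] == cb[gs - 1 + d]) --gs;
      while (ge + 1 <= hi && ca[ge + 1] >= 0 && cb[ge + 1 + d] >= 0 &&
             ca[ge + 1] == cb[ge + 1 + d]) ++ge;
      gap_done[d] = ge;

      // collect up to max_mm+1 mismatch-or-wall positions on each side
      std::vector<long> L(max_mm + 1), R(max_mm + 1);
      std::vector<bool> Lreal(max_mm + 1, false), Rreal(max_mm + 1, false);
      long p = gs - 1;
      bool walled = false;
      for (int t = 0; t <= max_mm; ++t) {
        if (walled || p < lo) { L[t] = walled ? L[t - 1] : lo - 1; walled = true; continue; }
        if (ca[p] < 0 || cb[p + d] < 0) {
          // N column: hard wall, not a countable mismatch
          L[t] = p; walled = true; continue;
        }
        L[t] = p; Lreal[t] = true;
        long q = p - 1;
        while (q >= lo && ca[q] >= 0 && cb[q + d] >= 0 && ca[q] == cb[q + d]) --q;
        p = q;
      }
      p = ge + 1;
      walled = false;
      for (int t = 0; t <= max_mm; ++t) {
        if (walled || p > hi) { R[t] = walled ? R[t - 1] : hi + 1; walled = true; continue; }
        if (ca[p] < 0 || cb[p + d] < 0) {
          R[t] = p; walled = true; continue;
        }
        R[t] = p; Rreal[t] = true;
        long q = p + 1;
        while (q <= hi && ca[q] >= 0 && cb[q + d] >= 0 && ca[q] == cb[q + d]) ++q;
        p = q;
      }
      // nothing to report if even the widest window is too short
      if (R[max_mm] - L[max_mm] - 1 < min_len) continue;
      // a wall (sequence end or N) blocks extension exactly like a
      // mismatch, but contributes nothing to the mismatch count
      for (int t = 0; t <= max_mm; ++t) {
        for (int u = 0; u <= max_mm; ++u) {
          int mm = 0;
          for (int x = 0; x < t; ++x) if (Lreal[x]) ++mm;
          for (int x = 0; x < u; ++x) if (Rreal[x]) ++mm;
          if (mm > max_mm) continue;
          long ws = L[t] + 1, we = R[u] - 1;
          long len = we - ws + 1;
          if (len < min_len) continue;
          uint64_t kk = ((uint64_t)(d + nb) << 42) |
                        ((uint64_t)ws << 21) | (uint64_t)we;
          if (seen.count(kk)) continue;
          seen.insert(kk);
          out_ia.push_back(ws);
          out_ib.push_back(ws + d);
          out_len.push_back(len);
          out_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["ia"] = out_ia, _["ib"] = out_ib,
                           _["len"] = out_len, _["mm"] = out_mm);
}
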