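#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>
#include <cstdint>
using namespace Rcpp;

// splitmix64: a fixed, documented 64-bit mixer used to hash canonical
// k-mer codes.  Output is truncated to 53 bits so hashes survive the trip
// through R doubles exactly.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Bottom-`size` distinct 53-bit hashes over canonical k-mers
// (canonical = min of 2-bit codes of the k-mer and its reverse complement).
// K-mers containing non-ACGT characters are skipped.
// [[Rcpp::export(name = ".minhash_bottom")]]
NumericVector minhash_bottom(std::string seq, int k, int size,
                             double seed) {
  int n = seq.size();
  std::vector<uint64_t> hashes;
  if (n < k || k < 1 || k > 31) return NumericVector(0);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  uint64_t hseed = splitmix64((uint64_t)seed + 0x5bd1e995ULL);
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      hashes.push_back(splitmix64(canon ^ hseed) >> 11); // 53 bits
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  int m = std::min<int>(size, hashes.size());
  NumericVector out(m);
  for (int i = 0; i < m; ++i) out[i] = (double)hashes[i];
  return out;
}
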