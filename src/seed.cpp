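#include <Rcpp.h>
#include <cstdint>

using namespace Rcpp;

// splitmix64-based seed derivation: mixes a base seed with a stream of
// integer labels (stage tags, sizes, iteration numbers) into a fresh
// sub-seed in [0, 2^31 - 1). Adding labels to the end of a stream never
// perturbs sub-seeds derived from shorter prefixes with different labels.

namespace {
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
} // namespace

// [[Rcpp::export(name = ".derive_seed_cpp")]]
int derive_seed_cpp(NumericVector parts) {
  uint64_t s = 0x8F1BBCDC2F9A7E1DULL;
  for (int i = 0; i < parts.size(); ++i) {
    s = splitmix64(s ^ (uint64_t)(int64_t)parts[i]);
  }
  return (int)(s % 2147483647ULL);
}
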