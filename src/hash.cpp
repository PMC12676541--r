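#include <Rcpp.h>
#include <cstdint>
#include <string>

using namespace Rcpp;

// splitmix64 finaliser: cheap, well-mixed 64-bit avalanche.
static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Seeded pseudo-random total order on k-mer strings: hash the bytes with a
// seed-dependent chain and map the top 53 bits to a double in [0, 1).
// [[Rcpp::export]]
NumericVector kmer_rank_cpp(CharacterVector kmers, double seed) {
  const uint64_t s0 = (uint64_t)(int64_t)seed;
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    uint64_t h = mix64(s0 ^ 0x8f1bbcdcbfa53e0bULL);
    for (char c : km) h = mix64(h ^ (uint64_t)(unsigned char)c);
    out[i] = (double)(h >> 11) / 9007199254740992.0; // 2^53
  }
  return out;
}
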