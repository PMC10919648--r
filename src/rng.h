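#ifndef COGSIM_RNG_H
#define COGSIM_RNG_H

#include <cstdint>
#include <cmath>

// Splittable counter-style generator: a splitmix64 stream keyed by
// (seed, key1, key2). Streams with distinct keys are independent for
// practical purposes and bit-reproducible across platforms.
struct SmRng {
  uint64_t s;
  bool have_spare;
  double spare;

  static inline uint64_t mix(uint64_t z) {
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  SmRng(uint64_t seed, uint64_t key1, uint64_t key2) {
    s = mix(seed + 0x9E3779B97F4A7C15ULL);
    s = mix(s ^ (key1 + 0xBF58476D1CE4E5B9ULL));
    s = mix(s ^ (key2 + 0x94D049BB133111EBULL));
    have_spare = false;
    spare = 0.0;
  }

  inline uint64_t next_u64() {
    s += 0x9E3779B97F4A7C15ULL;
    return mix(s);
  }

  // uniform on (0, 1)
  inline double runif() {
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal via Marsaglia's polar method (pairwise, cached)
  inline double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

#endif
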