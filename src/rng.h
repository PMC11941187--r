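#pragma once
#include <cstdint>
#include <cmath>

// Counter-seeded PRNG: each trajectory owns an independent substream derived
// deterministically from (seed, stream), so ensemble results are
// bit-reproducible and independent of execution order.

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

class Xoshiro256pp {
  uint64_t s[4];
  double cached_;
  bool has_cached_;
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

 public:
  Xoshiro256pp(uint64_t seed, uint64_t stream) : has_cached_(false) {
    SplitMix64 sm(seed ^ (0xD1B54A32D192ED03ULL * (stream + 1ULL)));
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in the open interval (0, 1); never exactly 0 or 1
  double runif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  // standard normal via Box-Muller, second deviate cached
  double rnorm() {
    if (has_cached_) {
      has_cached_ = false;
      return cached_;
    }
    double u1 = runif(), u2 = runif();
    double rad = std::sqrt(-2.0 * std::log(u1));
    double ang = 6.283185307179586476925287 * u2;
    cached_ = rad * std::sin(ang);
    has_cached_ = true;
    return rad * std::cos(ang);
  }
};
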