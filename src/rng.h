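#ifndef KNOTRELAX_RNG_H
#define KNOTRELAX_RNG_H

#include <cstdint>
#include <cmath>

// Deterministic RNG used by the integrator and the projection code.
// mt19937_64 plus Marsaglia polar gaussians: identical streams for a given
// seed regardless of the C++ standard library's distribution internals.
#include <random>

class KRng {
 public:
  explicit KRng(uint64_t seed) : eng_(mix(seed)), have_spare_(false), spare_(0.0) {}

  double unif() {  // (0, 1)
    uint64_t x = eng_();
    return (static_cast<double>(x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double gauss() {
    if (have_spare_) { have_spare_ = false; return spare_; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare_ = v * f;
    have_spare_ = true;
    return u * f;
  }

  // integer in [0, n)
  int below(int n) {
    return static_cast<int>(unif() * n) % n;
  }

 private:
  static uint64_t mix(uint64_t z) {  // splitmix64 scramble of the user seed
    z += 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  std::mt19937_64 eng_;
  bool have_spare_;
  double spare_;
};

#endif
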