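#pragma once
#include <cstdint>
#include <cmath>
#include <random>

// Deterministic RNG for the simulators. The mt19937_64 engine output is
// fully specified by the C++ standard, but the standard *distributions*
// are not; the transforms below are hand-rolled so that a seed alone
// reproduces a run on any standard library.
class Rng {
  std::mt19937_64 eng;
  double cached;
  bool has_cached;

public:
  explicit Rng(std::uint64_t seed) : eng(seed), cached(0.0), has_cached(false) {}

  // uniform on (0, 1), 53-bit resolution, never exactly 0 or 1
  double unif() {
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal via Marsaglia's polar method
  double normal() {
    if (has_cached) {
      has_cached = false;
      return cached;
    }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    cached = v * f;
    has_cached = true;
    return u * f;
  }

  // exponential with given mean (inversion)
  double expdist(double mean) { return -mean * std::log(unif()); }

  std::uint64_t raw() { return eng(); }
};
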