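#ifndef CASYNAPSE_RNG_H
#define CASYNAPSE_RNG_H

// Self-contained counter-seeded RNG so that every synapse / neuron owns an
// independent, order-invariant stream keyed by (global seed, entity id).
// xoshiro256++ (Blackman & Vigna) seeded through splitmix64, plus a
// 128-layer ziggurat normal sampler.

#include <cstdint>
#include <cmath>

namespace casyn {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Ziggurat {
  // x[0] is the virtual base-layer abscissa, x[1] = r, x[128] = 0.
  double x[129];
  double f[129];
  double r;
  Ziggurat() {
    r = 3.442619855899;
    const double v = 9.91256303526217e-3;
    x[0] = v * std::exp(0.5 * r * r);
    x[1] = r;
    x[128] = 0.0;
    for (int i = 2; i < 128; ++i) {
      double xi = x[i - 1];
      x[i] = std::sqrt(-2.0 * std::log(v / xi + std::exp(-0.5 * xi * xi)));
    }
    for (int i = 0; i <= 128; ++i) f[i] = std::exp(-0.5 * x[i] * x[i]);
  }
};

inline const Ziggurat &zigtab() {
  static const Ziggurat z;
  return z;
}

struct Rng {
  uint64_t s[4];

  Rng() { seed(0, 0); }
  Rng(uint64_t global_seed, uint64_t stream) { seed(global_seed, stream); }

  void seed(uint64_t global_seed, uint64_t stream) {
    // Mix seed and stream id so that nearby ids give uncorrelated states.
    uint64_t x = global_seed ^ (0x9E3779B97f4A7C15ULL * (stream + 1));
    s[0] = splitmix64(x);
    s[1] = splitmix64(x);
    s[2] = splitmix64(x);
    s[3] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
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

  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform in (0, 1]
  inline double unif_pos() { return ((next() >> 11) + 1.0) * 0x1.0p-53; }

  inline double expo(double rate) { return -std::log(unif_pos()) / rate; }

  // standard normal via ziggurat
  double norm() {
    const Ziggurat &Z = zigtab();
    for (;;) {
      uint64_t b = next();
      int i = static_cast<int>(b & 127);
      int64_t j = static_cast<int64_t>(b >> 10) - (1LL << 53);
      double u = j * 0x1.0p-53;  // (-1, 1)
      double z = u * Z.x[i];
      if (std::fabs(z) < Z.x[i + 1]) return z;
      if (i == 0) {
        // tail beyond r
        double xx, yy;
        do {
          xx = -std::log(unif_pos()) / Z.r;
          yy = -std::log(unif_pos());
        } while (yy + yy < xx * xx);
        return (z > 0) ? Z.r + xx : -(Z.r + xx);
      }
      double y = Z.f[i] + unif() * (Z.f[i + 1] - Z.f[i]);
      if (y < std::exp(-0.5 * z * z)) return z;
    }
  }

  int poisson(double lambda) {
    // inversion for small means, normal approx never needed here beyond ~1e6
    if (lambda <= 0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do {
        ++k;
        p *= unif_pos();
      } while (p > L);
      return k - 1;
    }
    // PTRS-lite: fall back to counting exponentials in chunks
    double t = 0.0;
    int k = 0;
    while ((t += expo(lambda)) < 1.0) ++k;
    return k;
  }
};

}  // namespace casyn

#endif
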