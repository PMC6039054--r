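#ifndef DEPRESSR_RNG_H
#define DEPRESSR_RNG_H

#include <cstdint>
#include <cmath>

// Single documented generator family for all compiled simulation code:
// xoshiro256++ seeded via splitmix64 from (seed, stream). Per-neuron /
// per-site substreams are derived deterministically from the stream index so
// that changing N or n does not alias randomness across units.
struct Xoshiro256 {
  uint64_t s[4];
  double spare;
  bool has_spare;

  static inline uint64_t splitmix64(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  Xoshiro256(uint64_t seed, uint64_t stream) : has_spare(false) {
    // mix seed and stream so that (seed, i) and (seed, j) are independent
    uint64_t x = seed ^ (stream * 0x9e3779b97f4a7c15ULL + 0x6a09e667f3bcc909ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;  // never all-zero
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform on (0, 1]
  inline double unif_pos() { return ((next() >> 11) + 1) * 0x1.0p-53; }

  // standard normal, Marsaglia polar method with cached spare
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f;
    has_spare = true;
    return u * f;
  }

  inline double expdev() { return -std::log(unif_pos()); }

  // 128-layer ziggurat for the standard normal (Marsaglia-Tsang layout,
  // tables built at first use from r and v below; layer areas all equal v,
  // strip 0 holds the tail). Falls back to the polar method while the
  // tables initialise. Used by the SDE samplers where normals dominate the
  // per-step cost; the polar method remains the reference implementation.
  static inline const double *zig_x() {
    static double xt[130];
    static bool ready = false;
    if (!ready) {
      const double r = 3.442619855899;
      const double v = 9.91256303526217e-3;
      double y = std::exp(-0.5 * r * r);  // y_1 = f(r)
      xt[0] = v / y;                      // base-strip width (includes tail)
      xt[1] = r;
      for (int i = 1; i < 128; ++i) {
        y += v / xt[i];
        if (y > 1.0) y = 1.0;  // guard against rounding at the top strip
        xt[i + 1] = std::sqrt(-2.0 * std::log(y));
      }
      xt[129] = 0.0;
      ready = true;
    }
    return xt;
  }

  inline double norm_zig() {
    const double *xt = zig_x();
    for (;;) {
      const uint64_t u = next();
      const int i = (int)(u & 127u);
      const double uf = ((u >> 11) * 0x1.0p-53) * 2.0 - 1.0;  // (-1, 1)
      const double x = uf * xt[i];
      if (std::fabs(x) < xt[i + 1]) return x;  // strictly inside layer i
      if (i == 0) {
        // tail beyond r (Marsaglia's method)
        const double r = xt[1];
        double xx, yy;
        do {
          xx = -std::log(unif_pos()) / r;
          yy = -std::log(unif_pos());
        } while (2.0 * yy < xx * xx);
        return uf > 0 ? r + xx : -(r + xx);
      }
      // wedge: accept under the density between the layer ordinates
      const double y0 = std::exp(-0.5 * xt[i] * xt[i]);
      const double y1 = std::exp(-0.5 * xt[i + 1] * xt[i + 1]);
      const double y = y0 + unif() * (y1 - y0);
      if (y < std::exp(-0.5 * x * x)) return x;
    }
  }

  // Marsaglia-Tsang; shape < 1 handled by the boost gamma(a+1) * U^{1/a}
  double rgamma(double a) {
    if (a < 1.0) {
      return rgamma(a + 1.0) * std::pow(unif_pos(), 1.0 / a);
    }
    const double d = a - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do {
        x = norm();
        v = 1.0 + c * x;
      } while (v <= 0.0);
      v = v * v * v;
      const double u = unif_pos();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
};

#endif
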