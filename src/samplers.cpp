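#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Gamma-distributed ISIs: shape alpha, mean rate `rate` (gamma rate alpha*rate).
// [[Rcpp::export]]
NumericVector cpp_gamma_isi(int n, double alpha, double rate,
                            double seed, double stream) {
  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  const double scale = 1.0 / (alpha * rate);
  for (int i = 0; i < n; ++i) out[i] = rng.rgamma(alpha) * scale;
  return out;
}

// First-passage ISIs of an LIF neuron, Euler-Maruyama with immediate reset.
// The absorbing threshold is lowered by 0.5826 * sigma * sqrt(2 dt / tau)
// (discrete-monitoring barrier correction) so the simulated first-passage
// times are unbiased to O(dt) rather than O(sqrt(dt)); disable with
// correct = false.
// [[Rcpp::export]]
NumericVector cpp_lif_isi(int n, double tau, double mu, double sigma,
                          double vth, double vre, double dt,
                          double seed, double stream, bool correct = true) {
  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  const double noise = sigma * std::sqrt(2.0 * dt / tau);
  const double vth_eff = correct ? vth - 0.5826 * noise : vth;
  const double fac = dt / tau;
  for (int i = 0; i < n; ++i) {
    double v = vre;
    double t = 0.0;
    for (;;) {
      v += fac * (mu - v) + noise * rng.norm_zig();
      t += dt;
      if (v >= vth_eff) break;
    }
    out[i] = t;
  }
  return out;
}

// First-passage ISIs of an EIF neuron (spike registered at vth, reset vre).
// Exponential term clipped at its value at vth to prevent overflow and
// tabulated on a fine voltage grid (linear interpolation; grid step
// min(0.01 mV, delta_T/25), relative error < 1e-4 of the term) for speed.
// [[Rcpp::export]]
NumericVector cpp_eif_isi(int n, double tau, double mu, double sigma,
                          double vth, double vre, double delta_T, double vT,
                          double dt, double seed, double stream,
                          bool correct = true) {
  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  const double noise = sigma * std::sqrt(2.0 * dt / tau);
  const double vth_eff = correct ? vth - 0.5826 * noise : vth;
  const double fac = dt / tau;
  const double arg_max = (vth - vT) / delta_T;
  // lookup table for delta_T * exp((v - vT)/delta_T) on [v0, vth]
  const double v0 = std::min(vre, mu) - 12.0 * sigma - 5.0;
  const double hv = std::min(0.01, delta_T / 25.0);
  const int ntab = (int)std::ceil((vth - v0) / hv) + 2;
  std::vector<double> tab(ntab);
  for (int k = 0; k < ntab; ++k) {
    double arg = (v0 + k * hv - vT) / delta_T;
    if (arg > arg_max) arg = arg_max;
    tab[k] = delta_T * std::exp(arg);
  }
  const double inv_hv = 1.0 / hv;
  for (int i = 0; i < n; ++i) {
    double v = vre;
    double t = 0.0;
    for (;;) {
      double ex;
      if (v <= v0) {
        ex = 0.0;  // far below threshold the spike term is negligible
      } else {
        const double s = (v - v0) * inv_hv;
        const int k = (int)s;
        const double w = s - k;
        ex = tab[k] + w * (tab[k + 1] - tab[k]);
      }
      v += fac * (mu - v + ex) + noise * rng.norm_zig();
      t += dt;
      if (v >= vth_eff) break;
    }
    out[i] = t;
  }
  return out;
}

// Raw draws from the compiled generator, exposed for statistical validation
// of the samplers themselves. kind: 0 = uniform, 1 = ziggurat normal,
// 2 = polar-method normal (reference), 3 = gamma(shape).
// [[Rcpp::export]]
NumericVector cpp_rng_draws(int n, int kind, double shape, double seed,
                            double stream) {
  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    switch (kind) {
    case 0: out[i] = rng.unif(); break;
    case 1: out[i] = rng.norm_zig(); break;
    case 2: out[i] = rng.norm(); break;
    default: out[i] = rng.rgamma(shape);
    }
  }
  return out;
}

// Event-driven release-site dynamics for n_sites independent sites sharing
// one spike train with the given ISI gaps. All sites start stocked. Per
// spike with preceding gap D an empty site restocks with probability
// 1 - exp(-lambda * D) (exact, no time discretisation); a stocked site
// releases with probability p and empties.
// Returns pre-spike occupancy and release indicators (n_spikes x n_sites).
// [[Rcpp::export]]
List cpp_site_release(NumericVector gaps, double p, double lambda,
                      int n_sites, double seed, double stream) {
  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);
  const int m = gaps.size();
  IntegerMatrix occ(m, n_sites);
  IntegerMatrix rel(m, n_sites);
  for (int j = 0; j < n_sites; ++j) {
    int stocked = 1;
    for (int i = 0; i < m; ++i) {
      if (!stocked) {
        const double p_restock = -std::expm1(-lambda * gaps[i]);
        if (rng.unif() < p_restock) stocked = 1;
      }
      occ(i, j) = stocked;
      if (stocked && rng.unif() < p) {
        rel(i, j) = 1;
        stocked = 0;
      }
    }
  }
  return List::create(_["occ_pre"] = occ, _["release"] = rel);
}
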