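#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Exact integration of tau dv/dt = mu - v + a tau sum_k delta(t - t_k):
// exponential relaxation towards mu between release events and an
// instantaneous jump a at each event. Voltage sampled on a regular grid
// t0, t0 + ds, ..., <= t1 (t0 acts as burn-in). Release times must be sorted.
// [[Rcpp::export]]
NumericVector cpp_voltage_samples(NumericVector times, double a, double tau,
                                  double mu, double t0, double t1, double ds) {
  const int n_samp = (int)std::floor((t1 - t0) / ds) + 1;
  NumericVector out(n_samp);
  double v = mu;      // start at rest; burn-in handles the transient
  double tcur = 0.0;
  int i = 0;          // next event index
  const int n_ev = times.size();
  for (int k = 0; k < n_samp; ++k) {
    const double ts = t0 + k * ds;
    while (i < n_ev && times[i] <= ts) {
      v = mu + (v - mu) * std::exp(-(times[i] - tcur) / tau);
      v += a;
      tcur = times[i];
      ++i;
    }
    out[k] = mu + (v - mu) * std::exp(-(ts - tcur) / tau);
  }
  return out;
}

// Euler integration of a post-synaptic EIF neuron driven by delta-impulse
// release events: tau dv/dt = mu - v + delta_T exp((v - vT)/delta_T), with a
// jump a per release, threshold vth -> reset vre. Spikes counted after t0.
// Returns c(spike_count, counted_duration).
// [[Rcpp::export]]
NumericVector cpp_post_eif(NumericVector times, double a, double tau,
                           double mu, double delta_T, double vT, double vth,
                           double vre, double dt, double t0, double t1) {
  const double arg_max = (vth - vT) / delta_T;
  double v = mu;
  double t = 0.0;
  int i = 0;
  const int n_ev = times.size();
  long count = 0;
  const double fac = dt / tau;
  while (t < t1) {
    double arg = (v - vT) / delta_T;
    if (arg > arg_max) arg = arg_max;
    v += fac * (mu - v + delta_T * std::exp(arg));
    t += dt;
    while (i < n_ev && times[i] <= t) {
      v += a;
      ++i;
    }
    if (v >= vth) {
      v = vre;
      if (t >= t0) ++count;
    }
  }
  return NumericVector::create((double)count, t1 - t0);
}
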