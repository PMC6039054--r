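---
title: "Short-term depression under correlated spike trains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term depression under correlated spike trains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depressr)
```

## The model

A release site holds at most one vesicle; its occupancy is the binary
variable $x(t)$. When a presynaptic spike arrives at a stocked site, the
vesicle is released with probability $p$ (and the site empties); empty sites
are restocked as a Poisson process of rate $\lambda$. Because $x$ is binary,
$\mathrm{Var}(x) = \langle x\rangle(1-\langle x\rangle)$ always.

The presynaptic spike train is a renewal process: inter-spike intervals
(ISIs) are i.i.d. with density $f(t)$ and rate $r = 1/\langle t\rangle$.
Everything the synapse statistics need from the drive enters through the
Laplace transform of the ISI density,
$$L(z) = \langle e^{-zt}\rangle = \int_0^\infty f(t)\,e^{-zt}\,dt,$$
which is why a single `isi_model` abstraction (rate, transform, sampler)
serves gamma-distributed ISIs and white-noise-driven leaky (LIF) and
exponential (EIF) integrate-and-fire neurons interchangeably.

Units are seconds, Hz and mV throughout. The default synapse is
$p = 0.6$, $\lambda = 2$ Hz; reference membrane parameters are
$\tau = 20$ ms, quantal amplitude $a = 0.3$ mV; the EIF uses
$\delta_T = 1.5$ mV, $v_T = 10$ mV and a registration threshold of
$v_{\rm th} = 15$ mV (exposed as a parameter: behaviour is insensitive to it
once it sits several $\delta_T$ above $v_T$, and a finite value keeps the
threshold-integration window bounded).

## Occupancy statistics

Two distinct occupancy means matter. The *pre-spike* mean
$\langle x\rangle_\infty$ (the probability the site is stocked when a spike
arrives) sets the release rate $\langle\chi\rangle = p r \langle
x\rangle_\infty$; the *time-averaged* mean $\langle x\rangle$ is tied to it
by the stationarity balance $\lambda(1-\langle x\rangle) = p r \langle
x\rangle_\infty$. For renewal drive,
$$\langle x\rangle_\infty = \frac{1 - L(\lambda)}{1 - qL(\lambda)},
\qquad q = 1 - p,$$
and the package evaluates every occupancy formula through `isi_laplace()`,
so there is no per-model occupancy code and the balance identity holds to
rounding error by construction. The general (non-renewal) series in terms of
multi-ISI expectations $\langle e^{-\lambda T_k}\rangle$ is exposed as
`general_prespike_mean()`, truncated once $q^k < 10^{-12}$ (geometric decay
bounds the tail; at $p = 1$ the closed single-term limit is used).

Two sites on the same axon see the same spikes, so their occupancies are
correlated even though release and restocking are independent; the joint
pre-spike mean $\langle xz\rangle_\infty$ and its covariance involve
$L(\lambda)$ and $L(2\lambda)$ only. Jensen's inequality
($L(2\lambda)\ge L(\lambda)^2$) makes the covariance non-negative for every
renewal model.

The bursty ($\alpha\to 0$) and regular ($\alpha\to\infty$) asymptotics for
gamma ISIs are provided with their stated validity ranges; calling the
bursty branch at $\alpha \ge 1$ warns rather than errors, since the formula
remains evaluable while $\lambda/(\alpha r) > 1$.

## Conditional rate kernels

The release autocovariance requires $G(t)$, the conditional rate of
spikes-arriving-at-a-stocked-site given a release (and thus an emptied site)
at time 0; the cross-covariance additionally requires $G'(t)$, identical
except that the site starts stocked. With
$g(t) = f(t)(1 - e^{-\lambda t})$ and $h(t) = f(t)e^{-\lambda t}$, the
kernels obey linear Volterra equations of the second kind,
$$F = f + F*f,\qquad G = g + F*g + q\,G*h,\qquad
(G'-G) = h + q\,(G'-G)*h,$$
where $F$ is the unconditional spike-triggered rate (renewal density) with
late-time limit $r$; $G \to r\langle x\rangle_\infty$ and $G'-G \to 0$.
In the Laplace domain all of these are closed forms in $L$
(`kernel_laplace()`), which is what the voltage variance uses; the
time-domain grids are needed for covariance curves and for validation.

### Numerical solution: product integration with analytic peeling

For bursty gamma shapes ($\alpha < 1$) the kernel $f \sim t^{\alpha-1}$
diverges at $0^+$, and an ordinary trapezoid discretisation of the Volterra
equations cannot deliver the accuracy we target. The solver therefore uses
*product integration*: the unknown is piecewise linear between grid points
while the kernel enters only through its exact panel moments
($\int$ and first moment of $f$, $g$, $h$ over each panel, computed from
`pgamma`). The integrable singularity is thus handled exactly, and the
error is governed by the smoothness of the unknown.

To make the unknown smooth, the first $M = \lceil 3/\alpha\rceil - 1$
renewal convolutions are peeled off analytically: $f^{*m}$ is again a gamma
density, and the remainder $F_M = \sum_{m > M} f^{*m}$ behaves like
$t^{(M+1)\alpha - 1}$ at the origin, i.e. at least $C^1$. The same peeling
applies to $G'-G$, whose series terms are scaled gamma densities in
$\beta + \lambda$. For $G$ the equation is rewritten for the regular part
$W = G - g$,
$$W = F*g + q\,(f*h - h*h) + q\,W*h,$$
with the mixed gamma convolution available in closed form,
$$f^{*m} * h = \mathrm{dgamma}(t;\,(m{+}1)\alpha,\,\beta)\;
{}_1F_1(\alpha;\,(m{+}1)\alpha;\,-\lambda t),$$
via the confluent hypergeometric function (implemented as a direct series
with the Kummer transformation for negative arguments and tested against its
Euler-integral form). These decompositions are carried inside the
`kernel_grid` objects, so the numerical Laplace transform
(`kernel_grid_laplace()`) integrates the analytic parts exactly, the smooth
remainder by the trapezoid rule, and the truncated tail as
$\text{asymptote}\cdot e^{-zT}/z$.

Grid defaults are $dt = 0.5$ ms and a horizon of
$\max(10/r,\,10/\lambda,\,2\,\mathrm{s})$; a diagnostic warns when the
late-time value has not settled on the known asymptote to $10^{-3}$
relative. The convergence tests in the suite run at $dt = 0.125$ ms, where
the series solutions and grid solvers agree to better than $10^{-6}$ Hz
sup-norm over two seconds.

For LIF/EIF drive the ISI density has no closed form; panel moments are
estimated from a large sample of simulated ISIs
(`empirical_density_moments()`), which is accurate at the Monte-Carlo level
used to validate those models' covariance curves.

### Dirac components

Point-process covariances carry a $\delta(t)$ at zero lag. It is never
discretised: `covariance_function` objects store `delta_weight` separately
from the continuous part. For bursty drive the *continuous* part itself has
an integrable $t^{\alpha-1}$ singularity at zero lag, so a binned simulation
estimate cannot be compared against a point value there; the objects
therefore also carry their gamma-component decomposition, and
`covariance_bin_average()` returns what a binned estimator measures — the
triangular-window average of the continuous part (exact incomplete-gamma
integrals for the singular components, weighted trapezoid for the smooth
remainder) plus `delta_weight / bin` in the zero-lag bin. Similarly the
zero-frequency $\pi\delta(\omega)$ components of the spectra are excluded
from `spectrum_grid`s (requesting $\omega = 0$ is an error that says so).

## Post-synaptic voltage moments and firing rate

For $N$ neurons each making $n$ independent contacts, the mean is
$\mu + a\tau Nn\,p r\langle x\rangle_\infty$ and the variance is the sum of
$Nn$ autocovariance terms and $Nn(n-1)$ shared-neuron cross-covariance
terms, evaluated from $L_G(1/\tau)$ and $L_{G'-G}(1/\tau)$. Both the direct
two-term expression and an algebraically rearranged form are implemented
(`voltage_variance()`, `voltage_variance_simplified()`) and asserted equal
to machine precision in the tests - a guard against transcription slips in
either form. At fixed $Nn$ the mean is independent of the split between
$N$ and $n$ while the variance grows with $n$: shared drive correlates
release sites.

The two-exponential EPSP generalisation ($n = 1$) replaces the single
membrane pole by the kernel's two time constants and recovers the delta-EPSP
forms as $\tau_2 \to 0$ (tested at $\tau_2 = 0.01$ ms to 0.5%).

The post-synaptic firing rate uses the *matched-variance* approximation:
the white-noise EIF steady-state rate evaluated at
$\mu_{\rm eff} = \langle v\rangle$, $\sigma_{\rm eff} = \mathrm{sd}(v)$.
With the $\sigma\sqrt{2\tau}\,\xi(t)$ noise convention, the stationary
threshold-free voltage variance of the white-noise model is exactly
$\sigma^2$, which fixes the mapping. A noise floor of
$\sigma_{\rm eff} = 0.01$ mV keeps the solver defined as the variance
vanishes, where the rate tends to the deterministic limit (0 Hz below the
rheobase $v_T - \delta_T$). In the reference configurations (10 Hz EIF
drive, $Nn = 1000$, intermediate-to-regular presynaptic statistics) the
approximation tracks full event-driven simulations to a few percent.

Its regime of validity has a sharp edge, documented here because the suite
exercises it: at the extreme bursting end of the sweep (presynaptic reset
*above* the spike-onset threshold, $\sigma = 2$ mV) with post-synaptic rest
at 0 mV, the post neuron sits $\sim$4 mV below rheobase and fires at well
under 1 Hz, driven by rare presynaptic bursts. The synaptic drive there is
strongly non-Gaussian and temporally correlated, and the white-noise
surrogate underestimates the rate several-fold even though the matched mean
and variance are exact (both verified against simulation). Matching two
moments is simply not sufficient information in a deeply subthreshold,
fluctuation-driven regime; treat matched-variance rates as quantitative only
when the operating point is within a couple of standard deviations of
rheobase or above.

## Integrate-and-fire first-passage machinery

*LIF.* The rate is the classical single-integral formula; the ISI transform
for real $z > 0$ is the ratio-of-integrals form in the reduced variable
$y$, whose integrable $y^{\tau z - 1}$ singularity is removed exactly by the
substitution $u = y^{\tau z}$ on $(0, 1]$. Integrands are rescaled by their
peak magnitude so deeply subthreshold parameters do not overflow;
$z = 0$ is evaluated as the $z = 10^{-8}$ limit (both integrals diverge
identically there and the ratio tends to 1). On the imaginary axis (needed
for spectra) the partial integration behind the $y^{\tau z-1}$ form is not
available, so the derivative form is integrated on a logarithmic grid where
the oscillations are uniform. The cylinder-function representation of this
transform is deliberately not used: one code path, no special functions.

*EIF.* Steady-state rate and first-passage transform are computed by
backward threshold integration on a voltage grid (default step 0.01 mV) from
`min(v_re, mu) - 10 sigma - 20` mV to $v_{\rm th}$: the density/flux pair is
integrated down from the absorbing threshold with an integrating-factor
update that is unconditionally stable in the stiff drift, the delta
re-injection enters at the reset, and $L(z)$ is read off as the flux ratio
that enforces decay at the lower boundary. Complex $z$ is supported by the
same sweep in complex arithmetic, with joint rescaling of the two solutions
to avoid overflow. The solver was validated against Euler-Maruyama
first-passage simulation (rates to 0.15%, transforms within Monte-Carlo
error).

*A note on the LIF limit.* As $\delta_T \to 0$ the EIF converges to the LIF
with threshold $v_T$, but slowly - the deviation scales like
$\delta_T\log(1/\delta_T)$, and at $\delta_T = 0.01$ mV the rate still
differs by 5-9% at typical operating points (verified against an SDE oracle
at $dt = 5\times 10^{-8}$ s). The suite asserts the monotone approach and
agreement at $\delta_T = 0.001$ mV; expectations of percent-level agreement
already at $\delta_T = 0.01$ mV are not borne out by the model pair.

## The simulator and what passing tests show

`simulate_transmission()` is event-driven at the synapse: restocking over a
gap $\Delta$ is resolved exactly with probability $1 - e^{-\lambda\Delta}$,
so the only discretisation anywhere is the Euler-Maruyama step
($dt = 0.01$ ms) inside the integrate-and-fire spike generators and the
post-synaptic EIF. The SDE samplers lower the absorbing threshold by
$0.5826\,\sigma\sqrt{2\,dt/\tau}$ (the discrete-monitoring barrier
correction), reducing the first-passage bias from $O(\sqrt{dt})$ to
$O(dt)$; without it the residual bias would be comparable to the
three-standard-error bands used at $10^6$ spikes. Voltage between release
events relaxes exponentially and is sampled exactly - no integration error
for delta EPSPs.

All compiled randomness comes from one generator family: xoshiro256++
seeded via splitmix64 from `(seed, stream)`, with polar-method and
128-layer ziggurat normals (the ziggurat is used in the SDE inner loops and
is itself under statistical test) and Marsaglia-Tsang gamma variates.
Neuron $i$ uses substream $2i$ for spikes and $2i+1$ for synaptic
randomness, so results are reproducible and independent across neurons for
any $N$, $n$.

The generator's defaults mirror the reference study conditions: synapse
$p = 0.6$, $\lambda = 2$ Hz; gamma drive at 5 Hz spanning bursty
($\alpha = 0.4$) to regular ($\alpha = 4$); LIF/EIF drive at 5-20 Hz with
reset/noise pairs spanning the same range of spiking statistics; and
$Nn = 1000$ synapses for the post-synaptic questions. Monte-Carlo
validations use $10^6$ presynaptic spikes for the distributional checks
(occupancy, covariances, spectra, voltage moments; three batch-means
standard errors), 300 s of simulated time for the shared-train voltage
checks and 100 s per configuration for the post-synaptic rate comparisons -
sizes chosen so statistical error sits well below the effects under test.
For the integrate-and-fire drives those million-spike checks halve the Euler
step to $5\,\mu$s: the zero-lag covariance bin has so small a standard error
at that sample size that the residual $O(dt)$ first-passage bias must be
pushed below it.
Passing these tests establishes agreement between the analytics and the
model's own stochastic dynamics; it says nothing about biological synapses
beyond the model's assumptions.

## Known limitations

- Renewal drive only: ISI correlations (e.g. from spike-frequency
  adaptation) are outside the analytics except through the generic series
  entry point for pre-spike occupancy.
- One vesicle per site, no facilitation, fixed quantal amplitude; the
  filtered-EPSP generalisation covers single contacts only.
- The matched-variance approximation delivers the post-synaptic *rate*, not
  its full ISI statistics.
- Time-domain kernels for integrate-and-fire drive rest on sampled ISI
  histograms (Monte-Carlo accuracy); their Laplace-domain counterparts are
  exact to solver tolerance.
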