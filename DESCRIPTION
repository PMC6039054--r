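Package: depressr
Title: Stochastic Short-Term Synaptic Depression with Renewal-Process
    Presynaptic Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytical and Monte-Carlo machinery for a quantal model of
    short-term synaptic depression in which binary vesicle release sites are
    depleted by probabilistic release and restocked at a memoryless rate,
    driven by renewal-process presynaptic spike trains (gamma-distributed
    inter-spike intervals or leaky/exponential integrate-and-fire neurons).
    Provides closed-form release-site occupancy statistics, spike- and
    release-triggered rate kernels obtained from Volterra integral equations
    and their Laplace-domain solutions, release auto- and cross-covariances
    and power spectra, post-synaptic voltage means and variances for multiple
    contacts and filtered synapses, a matched-variance approximation of the
    post-synaptic firing rate, and a seeded event-driven simulator used to
    validate every analytical result.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
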