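#' Feed-forward connectivity specification
#'
#' `N` statistically independent presynaptic neurons, each making `n`
#' independent release-site contacts onto the post-synaptic cell (sites on
#' the same neuron share its spike train and are therefore correlated), with
#' quantal EPSP amplitude `a`, post-synaptic membrane time constant `tau` and
#' resting potential `mu`.
#'
#' @param N presynaptic neuron count (positive integer)
#' @param n release sites per presynaptic neuron (positive integer)
#' @param a quantal EPSP amplitude in mV
#' @param tau post-synaptic membrane time constant in s
#' @param mu post-synaptic resting potential in mV
#' @return object of class `connectivity_spec`
#' @export
connectivity <- function(N = 1000, n = 1, a = 0.3, tau = 0.02, mu = 0) {
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(N = as.integer(N), n = as.integer(n), a = a, tau = tau,
                 mu = mu), class = "connectivity_spec")
}

#' @export
print.connectivity_spec <- function(x, ...) {
  cat(sprintf(
    "<connectivity> N = %d neurons x n = %d sites; a = %g mV, tau = %g s, mu = %g mV\n",
    x$N, x$n, x$a, x$tau, x$mu))
  invisible(x)
}

#' Mean post-synaptic voltage
#'
#' `<v> = mu + a tau N n p r <x>_inf`: the rest potential plus the shot-noise
#' mean of `N n` release trains of rate `<chi> = p r <x>_inf` filtered by the
#' membrane.
#'
#' @param conn a [connectivity()] spec
#' @param isi an `isi_model`
#' @param syn a [synapse()] object
#' @return mean voltage in mV
#' @export
voltage_mean <- function(conn, isi, syn) {
  conn$mu + conn$a * conn$tau * conn$N * conn$n * syn$p * isi_rate(isi) *
    prespike_occupancy_mean(isi, syn)
}

#' Post-synaptic voltage variance
#'
#' For single contacts (`n = 1`) the compact renewal form
#' `Var(v) = (tau N a^2 / 2) <chi> (1 + 2p [ (L(1/tau) - L(1/tau+lambda)) /
#'   ((1 - L(1/tau))(1 - q L(1/tau+lambda))) - tau r <x>_inf ])`.
#' For `n > 1` the `N n` autocovariance terms are joined by `N n (n-1)`
#' shared-neuron cross-covariance terms, weighted by the joint occupancy
#' `<xz>_inf` and the conditional kernels `L_G(1/tau)`, `L_{G'}(1/tau)`.
#' `voltage_variance_simplified()` evaluates the algebraically rearranged
#' form of the same result (used as an anti-typo cross-check; the two agree
#' to machine precision).
#'
#' @inheritParams voltage_mean
#' @return variance in mV^2
#' @export
voltage_variance <- function(conn, isi, syn) {
  r <- isi_rate(isi)
  tau <- conn$tau
  x_inf <- prespike_occupancy_mean(isi, syn)
  chi <- syn$p * r * x_inf
  LG <- kernel_laplace(1 / tau, isi, syn, which = "G")
  auto <- conn$N * conn$n * tau * conn$a^2 / 2 * chi *
    (1 + 2 * syn$p * (LG - tau * r * x_inf))
  if (conn$n == 1) return(auto)
  xz <- joint_prespike_occupancy(isi, syn)
  LD <- kernel_laplace(1 / tau, isi, syn, which = "Gdiff")
  cross <- conn$N * conn$n * (conn$n - 1) * tau * conn$a^2 / 2 *
    syn$p^2 * r * xz *
    (1 + 2 * (x_inf / xz) * (LG - tau * r * x_inf) + 2 * syn$q * LD)
  auto + cross
}

#' @rdname voltage_variance
#' @export
voltage_variance_simplified <- function(conn, isi, syn) {
  r <- isi_rate(isi)
  tau <- conn$tau
  q <- syn$q
  L1 <- isi_laplace(isi, 1 / tau)
  L2 <- isi_laplace(isi, 1 / tau + syn$lambda)
  x_inf <- prespike_occupancy_mean(isi, syn)
  xz <- joint_prespike_occupancy(isi, syn)
  chi <- syn$p * r * x_inf
  n <- conn$n
  pre <- tau * conn$a^2 * conn$N * n / 2 * chi
  line1 <- pre * (1 + 2 * syn$p * n *
                    ((L1 - L2) / ((1 - L1) * (1 - q * L2)) -
                       tau * r * x_inf))
  line2 <- pre * (n - 1) * syn$p * (xz / x_inf) *
    (1 + 2 * q * L2 / (1 - q * L2))
  line1 + line2
}

#' Post-synaptic voltage moments
#'
#' Bundles [voltage_mean()] and [voltage_variance()] into a `voltage_moments`
#' object, the input of [matched_variance_rate()].
#'
#' @inheritParams voltage_mean
#' @return object of class `voltage_moments` with fields `mean` (mV),
#'   `variance` (mV^2)
#' @export
voltage_moments <- function(conn, isi, syn) {
  m <- voltage_mean(conn, isi, syn)
  v <- voltage_variance(conn, isi, syn)
  if (v < 0) stop("negative voltage variance - inconsistent inputs")
  structure(list(mean = m, variance = v), class = "voltage_moments")
}

#' @export
print.voltage_moments <- function(x, ...) {
  cat(sprintf("<voltage moments> mean %.4f mV, sd %.4f mV (CV %.4f)\n",
              x$mean, sqrt(x$variance),
              if (x$mean != 0) sqrt(x$variance) / x$mean else NA))
  invisible(x)
}

#' Two-exponential EPSP kernel
#'
#' `E(t) = a (tau1 + tau2)/(tau1 - tau2) (exp(-t/tau1) - exp(-t/tau2))`,
#' a biophysically shaped EPSP with rise and decay time constants; its total
#' area is `a (tau1 + tau2)`. `tau1 = tau2` is a degenerate
#' (alpha-function) case that is not supported.
#'
#' @param a amplitude scale in mV
#' @param tau1,tau2 time constants in s (distinct, > 0)
#' @return object of class `epsp_kernel`
#' @export
epsp_kernel <- function(a = 0.3, tau1 = 0.02, tau2 = 0.002) {
  if (tau1 <= 0 || tau2 <= 0) stop("tau1 and tau2 must be > 0")
  if (tau1 == tau2) {
    stop("tau1 = tau2 is a degenerate kernel; use distinct time constants")
  }
  structure(list(a = a, tau1 = tau1, tau2 = tau2), class = "epsp_kernel")
}

#' Evaluate a two-exponential EPSP kernel
#'
#' @param kernel an [epsp_kernel()]
#' @param t times in s
#' @return EPSP values in mV (zero for `t < 0`)
#' @export
epsp_value <- function(kernel, t) {
  with(kernel, ifelse(t < 0, 0, a * (tau1 + tau2) / (tau1 - tau2) *
                        (exp(-t / tau1) - exp(-t / tau2))))
}

#' Voltage moments with filtered (two-exponential) EPSPs
#'
#' Generalisation of the delta-EPSP voltage moments to a shaped EPSP for
#' single-contact neurons (`n = 1`):
#' `<v> = mu + N <chi> a (tau1 + tau2)` and
#' `Var(v) = ((tau1 + tau2) N a^2 / 2) <chi> (1 + 2p [
#'   tau1 L_G(1/tau1)/(tau1 - tau2) + tau2 L_G(1/tau2)/(tau2 - tau1)
#'   - r <x>_inf (tau1 + tau2) ])`.
#' As `tau2 -> 0` the kernel tends to the exponential jump-`a` EPSP and the
#' moments recover the delta-EPSP forms with `tau = tau1`.
#'
#' @param kernel an [epsp_kernel()]
#' @param isi an `isi_model`
#' @param syn a [synapse()] object
#' @param N presynaptic neuron count (one release site each)
#' @param mu post-synaptic resting potential in mV
#' @return a `voltage_moments` object
#' @export
epsp_voltage_moments <- function(kernel, isi, syn, N = 1000, mu = 0) {
  r <- isi_rate(isi)
  x_inf <- prespike_occupancy_mean(isi, syn)
  chi <- syn$p * r * x_inf
  t1 <- kernel$tau1
  t2 <- kernel$tau2
  LG1 <- kernel_laplace(1 / t1, isi, syn, which = "G")
  LG2 <- kernel_laplace(1 / t2, isi, syn, which = "G")
  m <- mu + N * chi * kernel$a * (t1 + t2)
  v <- (t1 + t2) * N * kernel$a^2 / 2 * chi *
    (1 + 2 * syn$p * (t1 * LG1 / (t1 - t2) + t2 * LG2 / (t2 - t1) -
                        r * x_inf * (t1 + t2)))
  structure(list(mean = m, variance = v), class = "voltage_moments")
}

#' Matched-variance approximation of the post-synaptic firing rate
#'
#' Approximates the firing rate of an EIF neuron receiving the (temporally
#' correlated) depressing synaptic drive by the white-noise EIF rate with the
#' same stationary voltage mean and variance: the threshold-integration
#' steady rate is evaluated at `mu_eff = mean(v)` and
#' `sigma_eff = sd(v)`. With the `sigma sqrt(2 tau) xi(t)` noise
#' normalisation used throughout, the stationary (threshold-free) voltage
#' variance of the white-noise model equals `sigma^2`, which is what makes
#' this identification exact at the level of the first two moments.
#' Below rheobase with vanishing variance the rate is 0 Hz by construction.
#'
#' @param post an [eif_isi()] model carrying the post-synaptic cell's
#'   parameters (`tau`, `v_re`, `delta_T`, `v_T`, `v_th`; its `mu` and
#'   `sigma` are replaced by the matched moments)
#' @param moments a `voltage_moments` object
#' @return approximate firing rate in Hz
#' @export
matched_variance_rate <- function(post, moments) {
  stopifnot(inherits(post, "eif_isi"), inherits(moments, "voltage_moments"))
  # a small noise floor (0.01 mV) keeps the solver defined as variance -> 0,
  # where the rate tends to the deterministic limit (0 Hz below rheobase)
  sig <- max(sqrt(moments$variance), 0.01)
  m <- post
  m$mu <- moments$mean
  m$sigma <- sig
  eif_steady_rate(m)
}
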