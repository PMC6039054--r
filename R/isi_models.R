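#' Renewal ISI models
#'
#' Constructors for the renewal inter-spike-interval (ISI) models accepted by
#' every analytical routine in the package. All occupancy, kernel and voltage
#' formulas depend on the ISI law only through its Laplace transform
#' `L(z) = <exp(-z t)>`, so any of these models can be passed interchangeably.
#'
#' * `gamma_isi(shape, rate)`: gamma-distributed ISIs with density
#'   `f(t) = (alpha r)^alpha / Gamma(alpha) * t^(alpha-1) exp(-alpha r t)`.
#'   `shape < 1` gives bursty trains, `shape = 1` a Poisson process and
#'   `shape > 1` regular firing, at fixed mean rate `rate`.
#' * `lif_isi(mu, sigma, tau, v_th, v_re)`: first-passage ISIs of a leaky
#'   integrate-and-fire neuron driven by Gaussian white noise,
#'   `tau dv/dt = mu - v + sigma sqrt(2 tau) xi(t)`, threshold `v_th`,
#'   reset `v_re`.
#' * `eif_isi(mu, sigma, tau, v_re, delta_T, v_T, v_th)`: as above for the
#'   exponential integrate-and-fire neuron with spike-initiation term
#'   `delta_T exp((v - v_T)/delta_T)`; first-passage statistics are computed
#'   by threshold integration on a voltage grid of step `dv`.
#'
#' @param shape gamma shape parameter (dimensionless, > 0)
#' @param rate mean firing rate in Hz (> 0)
#' @param mu mean drive in mV
#' @param sigma noise standard deviation in mV (> 0)
#' @param tau membrane time constant in s (> 0)
#' @param v_th spike threshold in mV
#' @param v_re post-spike reset in mV (< `v_th`)
#' @param delta_T spike-onset sharpness in mV (> 0)
#' @param v_T spike-onset threshold in mV (< `v_th`)
#' @param dv voltage grid step in mV for the threshold-integration solver
#' @return an object of class `isi_model` exposing `isi_rate()`,
#'   `isi_laplace()` and `sample_isis()`
#' @examples
#' m <- gamma_isi(shape = 1, rate = 5)
#' isi_rate(m)
#' isi_laplace(m, 2)  # 5/7 for exponential ISIs
#' @export
gamma_isi <- function(shape, rate) {
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape),
            is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (shape <= 0) stop("gamma ISI shape must be > 0")
  if (rate <= 0) stop("gamma ISI rate must be > 0")
  structure(list(kind = "gamma", shape = shape, rate = rate),
            class = c("gamma_isi", "isi_model"))
}

#' @rdname gamma_isi
#' @export
lif_isi <- function(mu, sigma, tau = 0.02, v_th = 10, v_re = 0) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(tau),
            is.numeric(v_th), is.numeric(v_re))
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  if (v_re >= v_th) stop("v_re must be below v_th")
  m <- structure(list(kind = "lif", mu = mu, sigma = sigma, tau = tau,
                      v_th = v_th, v_re = v_re),
                 class = c("lif_isi", "isi_model"))
  m$rate <- lif_firing_rate(m)
  m
}

#' @rdname gamma_isi
#' @export
eif_isi <- function(mu, sigma, tau = 0.02, v_re = 0, delta_T = 1.5,
                    v_T = 10, v_th = 15, dv = 0.01) {
  stopifnot(is.numeric(mu), is.numeric(sigma))
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  if (delta_T <= 0) stop("delta_T must be > 0")
  if (v_th <= v_T) stop("v_th must lie above v_T")
  if (v_re >= v_th) stop("v_re must be below v_th")
  m <- structure(list(kind = "eif", mu = mu, sigma = sigma, tau = tau,
                      v_th = v_th, v_re = v_re, delta_T = delta_T,
                      v_T = v_T, dv = dv),
                 class = c("eif_isi", "isi_model"))
  m$rate <- eif_steady_rate(m)
  m
}

#' @export
print.isi_model <- function(x, ...) {
  cat(sprintf("<%s ISI model> rate = %.6g Hz\n", x$kind, isi_rate(x)))
  p <- x[setdiff(names(x), c("kind", "rate"))]
  cat(paste(sprintf("  %s = %g", names(p), unlist(p)), collapse = "\n"), "\n")
  invisible(x)
}

#' Mean firing rate of an ISI model
#'
#' The reciprocal of the mean inter-spike interval, in Hz.
#'
#' @param model an `isi_model`
#' @return firing rate in Hz
#' @export
isi_rate <- function(model) UseMethod("isi_rate")

#' @export
isi_rate.gamma_isi <- function(model) model$rate

#' @export
isi_rate.lif_isi <- function(model) model$rate

#' @export
isi_rate.eif_isi <- function(model) model$rate

#' ISI probability density
#'
#' Closed-form density of the ISI distribution. Available for gamma ISIs;
#' integrate-and-fire models expose only their Laplace transform and are
#' handled on a grid via [empirical_density_moments()].
#'
#' @param model an `isi_model`
#' @param t times in s (density is zero for `t <= 0`)
#' @return density values in 1/s
#' @export
isi_density <- function(model, t) UseMethod("isi_density")

#' @export
isi_density.gamma_isi <- function(model, t) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- dgamma(t[pos], shape = model$shape,
                     rate = model$shape * model$rate)
  out
}

#' @export
isi_density.isi_model <- function(model, t) {
  stop("no closed-form ISI density for '", model$kind,
       "' models; use empirical_density_moments() on sampled ISIs")
}

#' Laplace transform of the ISI density
#'
#' `L(z) = <exp(-z t)>`, the central quantity from which all occupancy and
#' release statistics are computed. `z` may be a non-negative real vector or
#' complex (for spectra, `z = 1i * omega`).
#'
#' For gamma ISIs the closed form `(alpha r / (z + alpha r))^alpha` is used.
#' For the LIF the transform is the ratio of two integrals in the reduced
#' variable `y`; the integrable `y^(tau z - 1)` singularity is removed by the
#' substitution `u = y^(tau z)` on (0, 1]. At purely imaginary argument the
#' pre-partial-integration (derivative) form is integrated on a log grid
#' instead. For the EIF the transform is obtained by backward threshold
#' integration of the Laplace-domain density/flux pair.
#'
#' @param model an `isi_model`
#' @param z Laplace argument(s) in 1/s; real `z >= 0` or complex
#' @return transform values, same length as `z`; real input gives values in
#'   (0, 1]
#' @export
isi_laplace <- function(model, z) UseMethod("isi_laplace")

#' @export
isi_laplace.gamma_isi <- function(model, z) {
  ar <- model$shape * model$rate
  if (is.complex(z)) {
    if (any(Re(z) <= -ar)) stop("need Re(z) > -shape*rate")
    return(exp(model$shape * (log(ar) - log(z + ar))))
  }
  if (any(z <= -ar)) stop("gamma ISI Laplace transform needs z > -shape*rate")
  (ar / (z + ar))^model$shape
}

#' @export
isi_laplace.lif_isi <- function(model, z) {
  if (is.complex(z)) {
    return(vapply(z, function(zz) lif_laplace_complex(model, zz),
                  complex(1)))
  }
  vapply(z, function(zz) lif_laplace_real(model, zz), numeric(1))
}

#' @export
isi_laplace.eif_isi <- function(model, z) {
  vlb <- eif_lower_bound(model)
  one <- function(zz) {
    L <- cpp_if_fpt_laplace(model$tau, model$mu, model$sigma, model$v_th,
                            model$v_re, model$delta_T, model$v_T, model$dv,
                            vlb, Re(zz), Im(zz))[1]
    if (is.complex(zz)) L else Re(L)
  }
  if (is.complex(z)) vapply(z, one, complex(1)) else vapply(z, one, numeric(1))
}

#' Sample i.i.d. inter-spike intervals
#'
#' Draws ISIs from the model's law: direct gamma sampling, or Euler-Maruyama
#' simulation of the underlying stochastic differential equation with
#' immediate reset for the integrate-and-fire models (time step `dt`, with a
#' discrete-monitoring threshold correction; see the methods vignette). All
#' randomness comes from a splitmix64-seeded xoshiro256++ generator; the same
#' `(seed, stream)` pair always yields the same draws.
#'
#' @param model an `isi_model`
#' @param n number of intervals
#' @param seed integer seed
#' @param stream substream index (used by the simulator to give each neuron
#'   an independent stream under one master seed)
#' @param dt Euler time step in s for the SDE samplers
#' @return numeric vector of `n` ISIs in s
#' @export
sample_isis <- function(model, n, seed, stream = 0, dt = 1e-5) {
  UseMethod("sample_isis")
}

#' @export
sample_isis.gamma_isi <- function(model, n, seed, stream = 0, dt = 1e-5) {
  cpp_gamma_isi(n, model$shape, model$rate, seed, stream)
}

#' @export
sample_isis.lif_isi <- function(model, n, seed, stream = 0, dt = 1e-5) {
  cpp_lif_isi(n, model$tau, model$mu, model$sigma, model$v_th, model$v_re,
              dt, seed, stream, TRUE)
}

#' @export
sample_isis.eif_isi <- function(model, n, seed, stream = 0, dt = 1e-5) {
  cpp_eif_isi(n, model$tau, model$mu, model$sigma, model$v_th, model$v_re,
              model$delta_T, model$v_T, dt, seed, stream, TRUE)
}

#' Sample a spike train
#'
#' Cumulative sum of [sample_isis()]: a strictly increasing vector of spike
#' times starting after time 0.
#'
#' @inheritParams sample_isis
#' @param n_spikes number of spikes (>= 1)
#' @return event-time vector in s (class `event_train`)
#' @export
sample_isi_train <- function(model, n_spikes, seed, stream = 0, dt = 1e-5) {
  stopifnot(n_spikes >= 1)
  event_train(cumsum(sample_isis(model, n_spikes, seed, stream, dt)))
}

#' Gamma ISI density (explicit form)
#'
#' Convenience wrapper evaluating the gamma ISI density
#' `(alpha r)^alpha / Gamma(alpha) t^(alpha-1) exp(-alpha r t)` for `t > 0`
#' and zero otherwise.
#'
#' @param t times in s
#' @param model a [gamma_isi()] model
#' @return density values in 1/s
#' @export
gamma_isi_density <- function(t, model) {
  stopifnot(inherits(model, "gamma_isi"))
  isi_density(model, t)
}

#' Gamma ISI Laplace transform (explicit form)
#'
#' `(alpha r / (z + alpha r))^alpha`; equals 1 at `z = 0`.
#'
#' @param z argument(s) in 1/s, `z > -shape*rate`
#' @param model a [gamma_isi()] model
#' @return transform values
#' @export
gamma_isi_laplace <- function(z, model) {
  stopifnot(inherits(model, "gamma_isi"))
  isi_laplace(model, z)
}

#' Mean ISI recovered from the Laplace transform
#'
#' Numerical `-dL/dz` at `z = 0` by step-halving extrapolation of forward
#' differences; used for consistency checks between the transform and the
#' firing-rate solvers.
#'
#' @param model an `isi_model`
#' @param eps base step as a fraction of the firing rate
#' @return mean ISI in s
#' @export
isi_mean_from_laplace <- function(model, eps = 1e-2) {
  r <- isi_rate(model)
  h <- eps * r
  m1 <- (1 - isi_laplace(model, h)) / h
  m2 <- (1 - isi_laplace(model, h / 2)) / (h / 2)
  2 * m2 - m1
}

# ---- LIF quadrature ---------------------------------------------------------

#' Firing rate of the white-noise-driven LIF neuron
#'
#' Evaluates the single-integral form
#' `1/(r tau) = int_0^inf dy/y exp(-y^2/2) (exp(y y_th) - exp(y y_re))`
#' with `y_th = (v_th - mu)/sigma`, `y_re = (v_re - mu)/sigma`. The integrand
#' is rescaled by its peak magnitude to avoid overflow; far below threshold
#' (`y_th > 25`) the saddle-point form of the integral is used, where the
#' rate is numerically zero anyway.
#'
#' @param model a [lif_isi()] model (the cached rate is ignored; the integral
#'   is evaluated from the parameters)
#' @return firing rate in Hz
#' @export
lif_firing_rate <- function(model) {
  y_th <- (model$v_th - model$mu) / model$sigma
  y_re <- (model$v_re - model$mu) / model$sigma
  if (y_th > 25) {
    # deep sub-threshold: Kramers/saddle-point evaluation of the integral
    log_I <- y_th^2 / 2 + 0.5 * log(2 * pi) - log(y_th)
    return(exp(-log_I) / model$tau)
  }
  shift <- if (y_th > 0) y_th^2 / 2 else 0  # peak magnitude of the integrand
  f <- function(y) {
    ifelse(y == 0, (y_th - y_re) * exp(-shift),
           (exp(y * y_th - y^2 / 2 - shift) -
              exp(y * y_re - y^2 / 2 - shift)) / y)
  }
  upper <- max(10, y_th + 10)
  I1 <- integrate(f, 0, upper, rel.tol = 1e-10, abs.tol = 0)
  I2 <- integrate(f, upper, Inf, rel.tol = 1e-8)
  I <- (I1$value + I2$value) * exp(shift)
  if (!is.finite(I) || I <= 0) {
    stop("LIF rate quadrature failed (integral = ", I, ")")
  }
  1 / (model$tau * I)
}

# log of I(nu, c) = int_0^inf y^(nu-1) exp(-y^2/2 + c y) dy, nu > 0.
# Split at y = 1; on (0,1] substitute u = y^nu which removes the integrable
# singularity exactly; adaptive quadrature on [1, Inf). Rescaled by the peak
# magnitude exp(c^2/2) when c > 0 to avoid overflow.
lif_log_integral <- function(nu, cc) {
  shift <- if (cc > 0) cc^2 / 2 else 0
  g1 <- function(u) {
    y <- exp(log(u) / nu)  # u^(1/nu), stable for tiny nu
    exp(-y^2 / 2 + cc * y - shift)
  }
  p1 <- integrate(g1, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value / nu
  g2 <- function(y) exp((nu - 1) * log(y) - y^2 / 2 + cc * y - shift)
  p2 <- integrate(g2, 1, Inf, rel.tol = 1e-11, abs.tol = 0)$value
  log(p1 + p2) + shift
}

# L(z) for real z via the integral-ratio form; z = 0 evaluated as the limit
# at z = 1e-8 (both integrals diverge identically there).
lif_laplace_real <- function(model, z) {
  if (z < 0) stop("LIF ISI Laplace transform requires z >= 0")
  if (z == 0) z <- 1e-8
  nu <- model$tau * z
  y_th <- (model$v_th - model$mu) / model$sigma
  y_re <- (model$v_re - model$mu) / model$sigma
  exp(lif_log_integral(nu, y_re) - lif_log_integral(nu, y_th))
}

# Complex z (spectra): the partial-integration step behind the y^(nu-1) form
# is not available on the imaginary axis, so integrate the derivative form
# int_0^inf y^(i w tau) d/dy[exp(c y - y^2/2)] dy on a log grid
# (y = exp(u)), where the oscillations in u are uniform.
lif_laplace_complex <- function(model, z) {
  nu <- model$tau * z
  y_th <- (model$v_th - model$mu) / model$sigma
  y_re <- (model$v_re - model$mu) / model$sigma
  one <- function(cc) {
    # int_0^inf y^nu d/dy[e^{cy - y^2/2}] dy on the log grid y = e^u;
    # rescaled by the integrand peak exp(shift) to avoid overflow
    shift <- if (cc > 0) cc^2 / 2 else 0
    h <- function(u, part) {
      y <- exp(u)
      w <- (cc - y) * exp(cc * y - y^2 / 2 - shift) * y  # extra y: du measure
      ph <- Im(nu) * u  # y^{i Im(nu)} = e^{i Im(nu) u}
      amp <- if (Re(nu) != 0) exp(Re(nu) * u) else 1
      if (part == "re") w * amp * cos(ph) else w * amp * sin(ph)
    }
    lo <- -60
    hi <- log(max(10, abs(cc) + 10))
    re <- integrate(h, lo, hi, part = "re", rel.tol = 1e-10, abs.tol = 1e-12,
                    subdivisions = 2000L)$value
    im <- integrate(h, lo, hi, part = "im", rel.tol = 1e-10, abs.tol = 1e-12,
                    subdivisions = 2000L)$value
    list(value = complex(real = re, imaginary = im), shift = shift)
  }
  num <- one(y_re)
  den <- one(y_th)
  (num$value / den$value) * exp(num$shift - den$shift)
}

#' Drive giving a target LIF firing rate
#'
#' Root-finds the mean drive `mu` at which the LIF rate equals
#' `rate_hz`, the procedure used to hold presynaptic rates constant while
#' reset and noise are varied.
#'
#' @param rate_hz target rate in Hz
#' @param sigma,tau,v_th,v_re LIF parameters (mV, s, mV, mV)
#' @return a [lif_isi()] model with the fitted `mu`
#' @export
lif_for_rate <- function(rate_hz, sigma, tau = 0.02, v_th = 10, v_re = 0) {
  f <- function(mu) {
    lif_firing_rate(list(mu = mu, sigma = sigma, tau = tau,
                         v_th = v_th, v_re = v_re)) - rate_hz
  }
  lo <- v_re - 20
  hi <- v_th + 30
  mu <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  lif_isi(mu = mu, sigma = sigma, tau = tau, v_th = v_th, v_re = v_re)
}

# ---- EIF threshold integration ---------------------------------------------

eif_lower_bound <- function(model) {
  min(model$v_re, model$mu) - 10 * model$sigma - 20
}

#' Steady-state firing rate of the white-noise-driven EIF neuron
#'
#' Backward integration of the stationary density from the absorbing
#' threshold with unit flux above the reset; the rate is the reciprocal of
#' the integrated density. The voltage grid runs from
#' `min(v_re, mu) - 10 sigma - 20` mV up to `v_th` with step `dv`.
#'
#' @param model an [eif_isi()] model (or a parameter list with the same
#'   fields)
#' @return firing rate in Hz
#' @export
eif_steady_rate <- function(model) {
  r <- cpp_if_steady_rate(model$tau, model$mu, model$sigma, model$v_th,
                          model$v_re, model$delta_T, model$v_T,
                          if (is.null(model$dv)) 0.01 else model$dv,
                          eif_lower_bound(model))
  if (!is.finite(r) || r < 0) stop("EIF threshold integration failed")
  r
}

#' Laplace transform of the EIF first-passage density
#'
#' Convenience wrapper around [isi_laplace()] for EIF models, with a
#' normalisation check: the solver must return `L(0) = 1` within `tol`.
#'
#' @param z argument(s), real `>= 0` or complex
#' @param model an [eif_isi()] model
#' @param tol tolerance for the `L(0)` normalisation diagnostic
#' @return transform values
#' @export
eif_isi_laplace <- function(z, model, tol = 1e-4) {
  L0 <- isi_laplace(model, 0)
  if (abs(L0 - 1) > tol) {
    stop("EIF solver normalisation off: L(0) = ", format(L0),
         "; refine the voltage grid (dv)")
  }
  isi_laplace(model, z)
}

#' @rdname lif_for_rate
#' @param v_re_eif,delta_T,v_T,v_th_eif EIF parameters in mV
#' @export
eif_for_rate <- function(rate_hz, sigma, tau = 0.02, v_re_eif = 0,
                         delta_T = 1.5, v_T = 10, v_th_eif = 15) {
  f <- function(mu) {
    cpp_if_steady_rate(tau, mu, sigma, v_th_eif, v_re_eif, delta_T, v_T,
                       0.01, min(v_re_eif, mu) - 10 * sigma - 20) - rate_hz
  }
  mu <- uniroot(f, c(v_re_eif - 25, v_T + 30), tol = 1e-10)$root
  eif_isi(mu = mu, sigma = sigma, tau = tau, v_re = v_re_eif,
          delta_T = delta_T, v_T = v_T, v_th = v_th_eif)
}

#' LIF ISI Laplace transform (explicit form)
#'
#' The ratio-of-integrals form of the first-passage-time transform for real
#' `z >= 0` (the `z = 0` limit equals 1).
#'
#' @param z argument(s) in 1/s
#' @param model a [lif_isi()] model
#' @return transform values in (0, 1]
#' @export
lif_isi_laplace <- function(z, model) {
  stopifnot(inherits(model, "lif_isi"))
  isi_laplace(model, z)
}
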