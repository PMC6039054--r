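#' Confluent hypergeometric function 1F1 (Kummer)
#'
#' Series evaluation of `1F1(a; b; x)`, used for the closed-form convolution
#' of gamma renewal densities with the exponentially tilted density that
#' appears in the release-kernel forcing terms. For `x < 0` the Kummer
#' transformation `1F1(a;b;x) = exp(x) 1F1(b-a; b; -x)` is applied so the
#' series has positive terms (no cancellation).
#'
#' @param a,b parameters (`b > 0`)
#' @param x argument vector
#' @param tol relative series tolerance
#' @return values of `1F1(a; b; x)`
#' @export
kummer_1f1 <- function(a, b, x, tol = 1e-15) {
  stopifnot(b > 0)
  neg <- x < 0
  xx <- abs(x)
  a_pos <- b - a
  out <- numeric(length(x))
  # evaluate series 1F1(a*; b; xx) with xx >= 0, a* depends on sign group
  for (grp in unique(neg)) {
    sel <- neg == grp
    av <- if (grp) a_pos else a
    z <- xx[sel]
    term <- rep(1, length(z))
    s <- rep(1, length(z))
    k <- 0
    repeat {
      k <- k + 1
      term <- term * (av + k - 1) / ((b + k - 1) * k) * z
      s <- s + term
      if (all(abs(term) <= tol * abs(s))) break
      if (k > 2000) stop("1F1 series failed to converge")
    }
    out[sel] <- if (grp) exp(-z) * s else s
  }
  out
}

# ---- gamma panel moments ----------------------------------------------------

# Exact panel moments of a gamma(shape, rate) density on a uniform grid:
# m0[j] = mass of panel j, w1[j] = (1/dt) * first moment about the panel's
# left edge. These let the Volterra sweep treat the integrable t^(shape-1)
# singularity exactly.
gamma_panel_moments <- function(shape, rate, dt, n_panels, weight = 1) {
  edges <- seq(0, n_panels * dt, by = dt)
  P0 <- pgamma(edges, shape = shape, rate = rate)
  P1 <- pgamma(edges, shape = shape + 1, rate = rate)
  m0 <- weight * diff(P0)
  m1 <- weight * (shape / rate) * diff(P1)
  w1 <- (m1 - edges[-length(edges)] * m0) / dt
  list(m0 = m0, w1 = w1)
}

#' Empirical ISI panel moments
#'
#' Builds the panel masses and first moments of the ISI density `f`, the
#' restocked-before-next-spike density `g(t) = f(t)(1 - exp(-lambda t))` and
#' its complement `h(t) = f(t) exp(-lambda t)` from a sample of ISIs, for use
#' by the kernel solvers when the ISI law has no closed-form density
#' (integrate-and-fire presynaptic neurons). Grid-point density estimates use
#' centred bins of width `dt`.
#'
#' @param isis numeric vector of sampled ISIs in s
#' @param dt grid step in s
#' @param tmax grid horizon in s (ISIs beyond it carry no weight inside the
#'   solved window)
#' @param lambda restock rate in Hz (for the `g`/`h` splits); `NULL` for
#'   `f`-only moments
#' @return list with `m0f`, `w1f`, `fgrid` and, when `lambda` is given,
#'   `m0g`, `w1g`, `ggrid`, `m0h`, `w1h`, `hgrid`
#' @export
empirical_density_moments <- function(isis, dt, tmax, lambda = NULL) {
  n <- length(isis)
  if (n < 1000) stop("need a reasonably large ISI sample (>= 1000)")
  N <- round(tmax / dt)
  inside <- isis < N * dt
  x <- isis[inside]
  panel <- floor(x / dt) + 1L          # 1-based panel index
  frac <- (x / dt - (panel - 1L))      # position within panel, [0,1)
  agg <- function(wts) {
    m0 <- as.numeric(tapply(wts, factor(panel, levels = 1:N), sum))
    m0[is.na(m0)] <- 0
    w1 <- as.numeric(tapply(wts * frac, factor(panel, levels = 1:N), sum))
    w1[is.na(w1)] <- 0
    list(m0 = m0 / n, w1 = w1 / n)
  }
  gridval <- function(wts) {
    # centred-bin density estimate at grid points t_i = i*dt, i = 1..N
    cpanel <- pmin(N, pmax(1L, floor(x / dt + 0.5) + 1L))
    gv <- as.numeric(tapply(wts, factor(cpanel, levels = 1:N), sum))
    gv[is.na(gv)] <- 0
    gv / (n * dt)
  }
  fm <- agg(rep(1, length(x)))
  out <- list(m0f = fm$m0, w1f = fm$w1, fgrid = gridval(rep(1, length(x))),
              dt = dt, tmax = N * dt)
  if (!is.null(lambda)) {
    wh <- exp(-lambda * x)
    hm <- agg(wh)
    out$m0h <- hm$m0
    out$w1h <- hm$w1
    out$hgrid <- gridval(wh)
    out$m0g <- fm$m0 - hm$m0
    out$w1g <- fm$w1 - hm$w1
    out$ggrid <- out$fgrid - out$hgrid
  }
  out
}

# ---- kernel grids -----------------------------------------------------------

new_kernel_grid <- function(t, values, dt, tmax, asymptote, kind,
                            analytic = NULL, remainder = NULL, x0 = 0,
                            tail_tol = 1e-3) {
  if (any(!is.finite(values))) stop("kernel grid contains non-finite values")
  g <- structure(list(t = t, values = values, dt = dt, tmax = tmax,
                      asymptote = asymptote, kind = kind,
                      analytic = analytic, remainder = remainder, x0 = x0),
                 class = "kernel_grid")
  # horizon diagnostic: the late-time value must have settled on the
  # asymptote (relative for kernels with non-zero limits, absolute for decays)
  n <- length(values)
  tail_dev <- if (asymptote > 0) {
    abs(values[n] - asymptote) / asymptote
  } else {
    abs(values[n]) / max(abs(values), 1e-300)
  }
  if (tail_dev > tail_tol) {
    warning(sprintf("kernel %s has not reached its asymptote at tmax ",
                    kind), sprintf("(relative deviation %.2g); ", tail_dev),
            "increase tmax")
  }
  g
}

#' @export
print.kernel_grid <- function(x, ...) {
  cat(sprintf("<kernel grid %s> dt = %g s, tmax = %g s, asymptote = %g Hz\n",
              x$kind, x$dt, x$tmax, x$asymptote))
  invisible(x)
}

# number of renewal-convolution terms peeled off analytically so the Volterra
# unknown is smooth at t = 0 (the remainder behaves like t^((M+1)*shape - 1))
gamma_peel_terms <- function(shape) max(0L, as.integer(ceiling(3 / shape)) - 1L)

# sum of peeled analytic components (weight * dgamma(shape, rate)) at times t
analytic_component_values <- function(analytic, t) {
  if (is.null(analytic) || nrow(analytic) == 0) return(numeric(length(t)))
  v <- numeric(length(t))
  for (i in seq_len(nrow(analytic))) {
    v <- v + analytic$weight[i] *
      dgamma(t, shape = analytic$shape[i], rate = analytic$rate[i])
  }
  v
}

#' Spike-triggered presynaptic rate F(t)
#'
#' Solves the renewal integral equation
#' `F(t) = f(t) + int_0^t F(s) f(t-s) ds`
#' for the probability density of a spike at `t` given a spike at 0, on a
#' uniform grid. The solver uses product integration: the unknown is
#' piecewise linear while the kernel enters via exact panel moments, and for
#' gamma ISIs the first few renewal convolutions `f^(*m)` (gamma densities)
#' are handled analytically so the remaining unknown is smooth at 0 even for
#' bursty shapes `alpha < 1` where `f` diverges. `F(t) -> r` at late times.
#'
#' @param isi an `isi_model`
#' @param dt grid step in s (default 0.5 ms)
#' @param tmax horizon in s; defaults to `max(10/r, 2)`
#' @param moments optional [empirical_density_moments()] output for models
#'   without a closed-form density
#' @return a `kernel_grid`
#' @export
solve_spike_triggered_rate <- function(isi, dt = 5e-4, tmax = NULL,
                                       moments = NULL) {
  r <- isi_rate(isi)
  if (is.null(tmax)) tmax <- max(10 / r, 2)
  N <- round(tmax / dt)
  t <- dt * seq_len(N)
  if (inherits(isi, "gamma_isi")) {
    a <- isi$shape
    beta <- a * r
    M <- gamma_peel_terms(a)
    fm <- gamma_panel_moments(a, beta, dt, N)
    b <- dgamma(t, shape = (M + 1) * a, rate = beta)
    rem <- cpp_volterra_sweep(b, fm$m0, fm$w1, 1, 0)
    analytic <- if (M > 0) {
      data.frame(weight = rep(1, M), shape = (1:M) * a,
                 rate = rep(beta, M))
    } else NULL
    vals <- rem + analytic_component_values(analytic, t)
    return(new_kernel_grid(t, vals, dt, N * dt, asymptote = r, kind = "F",
                           analytic = analytic, remainder = rem))
  }
  if (is.null(moments)) {
    stop("no closed-form ISI density for '", isi$kind, "' models; supply ",
         "`moments` from empirical_density_moments()")
  }
  rem <- cpp_volterra_sweep(moments$fgrid, moments$m0f, moments$w1f, 1, 0)
  new_kernel_grid(t, rem, dt, N * dt, asymptote = r, kind = "F",
                  remainder = rem, tail_tol = 5e-3)
}

#' Release-triggered conditional spike rate G(t)
#'
#' Solves
#' `G(t) = g(t) + int_0^t F(s) g(t-s) ds + q int_0^t G(s) h(t-s) ds`
#' with `g = f (1 - exp(-lambda t))`, `h = f exp(-lambda t)`: the density of
#' a spike arriving at `t` with the site stocked, given a release (site
#' emptied) at 0. `p G(t)` is the release-conditioned release rate;
#' `G(t) -> r <x>_inf`. For gamma ISIs the forcing convolution `F * g` uses
#' the peeled renewal terms in closed form (gamma-gamma convolutions via the
#' confluent hypergeometric function) plus product integration of the smooth
#' remainder.
#'
#' @inheritParams solve_spike_triggered_rate
#' @param syn a [synapse()] object
#' @param F_grid optional precomputed [solve_spike_triggered_rate()] result
#'   on the same grid
#' @return a `kernel_grid`
#' @export
solve_release_triggered_rate <- function(isi, syn, dt = 5e-4, tmax = NULL,
                                         moments = NULL, F_grid = NULL) {
  r <- isi_rate(isi)
  lam <- syn$lambda
  if (is.null(tmax)) tmax <- max(10 / r, 10 / lam, 2)
  N <- round(tmax / dt)
  t <- dt * seq_len(N)
  x_inf <- prespike_occupancy_mean(isi, syn)
  if (is.null(F_grid)) {
    F_grid <- solve_spike_triggered_rate(isi, dt, tmax, moments = moments)
  }
  stopifnot(length(F_grid$values) == N)

  if (inherits(isi, "gamma_isi")) {
    # solve for the regular part W = G - g (the singular g is carried
    # analytically): W = F*g + q (f*h - h*h) + q W*h
    a <- isi$shape
    beta <- a * r
    Llam <- (beta / (beta + lam))^a
    fm <- gamma_panel_moments(a, beta, dt, N)
    hm <- gamma_panel_moments(a, beta + lam, dt, N, weight = Llam)
    m0g <- fm$m0 - hm$m0
    w1g <- fm$w1 - hm$w1
    gvals <- dgamma(t, a, rate = beta) * (1 - exp(-lam * t))
    # F * g = sum_m [f^(m+1) - f^(m) * h] + F_remainder * g, with
    # f^(m) * h = dgamma((m+1)a, beta) 1F1(a; (m+1)a; -lam t) in closed form
    conv <- cpp_product_convolve(F_grid$remainder, 0, m0g, w1g)
    M <- if (is.null(F_grid$analytic)) 0L else nrow(F_grid$analytic)
    if (M > 0) {
      for (m in 1:M) {
        conv <- conv + dgamma(t, (m + 1) * a, rate = beta) *
          (1 - kummer_1f1(a, (m + 1) * a, -lam * t))
      }
    }
    fh <- dgamma(t, 2 * a, rate = beta) * kummer_1f1(a, 2 * a, -lam * t)
    hh <- Llam^2 * dgamma(t, 2 * a, rate = beta + lam)
    b <- conv + syn$q * (fh - hh)
    W <- cpp_volterra_sweep(b, hm$m0, hm$w1, syn$q, 0)
    analytic <- data.frame(weight = c(1, -Llam), shape = c(a, a),
                           rate = c(beta, beta + lam))
    return(new_kernel_grid(t, gvals + W, dt, N * dt, asymptote = r * x_inf,
                           kind = "G", analytic = analytic, remainder = W))
  }
  if (is.null(moments)) {
    stop("supply `moments` from empirical_density_moments() for '",
         isi$kind, "' models")
  }
  conv <- cpp_product_convolve(F_grid$values, 0, moments$m0g, moments$w1g)
  b <- moments$ggrid + conv
  G <- cpp_volterra_sweep(b, moments$m0h, moments$w1h, syn$q, 0)
  new_kernel_grid(t, G, dt, N * dt, asymptote = r * x_inf, kind = "G",
                  tail_tol = 5e-3)
}

#' Occupancy-conditioned kernel difference G'(t) - G(t)
#'
#' The kernel `G'` conditions on the site being stocked (rather than emptied)
#' just after the spike at 0; only the difference `D = G' - G` enters the
#' release cross-covariance, and it obeys the simpler equation
#' `D(t) = h(t) + q int_0^t D(s) h(t-s) ds` with `D -> 0`.
#'
#' @inheritParams solve_release_triggered_rate
#' @return a `kernel_grid` (kind `"Gdiff"`)
#' @export
solve_release_rate_difference <- function(isi, syn, dt = 5e-4, tmax = NULL,
                                          moments = NULL) {
  r <- isi_rate(isi)
  lam <- syn$lambda
  q <- syn$q
  if (is.null(tmax)) tmax <- max(10 / r, 10 / lam, 2)
  N <- round(tmax / dt)
  t <- dt * seq_len(N)
  if (inherits(isi, "gamma_isi")) {
    a <- isi$shape
    beta <- a * r
    Llam <- (beta / (beta + lam))^a
    hm <- gamma_panel_moments(a, beta + lam, dt, N, weight = Llam)
    M <- gamma_peel_terms(a)
    b <- q^M * Llam^(M + 1) * dgamma(t, (M + 1) * a, rate = beta + lam)
    rem <- cpp_volterra_sweep(b, hm$m0, hm$w1, q, 0)
    analytic <- if (M > 0) {
      data.frame(weight = q^(0:(M - 1)) * Llam^(1:M), shape = (1:M) * a,
                 rate = rep(beta + lam, M))
    } else NULL
    vals <- rem + analytic_component_values(analytic, t)
    return(new_kernel_grid(t, vals, dt, N * dt, asymptote = 0,
                           kind = "Gdiff", analytic = analytic,
                           remainder = rem))
  }
  if (is.null(moments)) {
    stop("supply `moments` from empirical_density_moments() for '",
         isi$kind, "' models")
  }
  rem <- cpp_volterra_sweep(moments$hgrid, moments$m0h, moments$w1h, q, 0)
  new_kernel_grid(t, rem, dt, N * dt, asymptote = 0, kind = "Gdiff",
                  remainder = rem, tail_tol = 5e-3)
}

#' Series solution for F(t) with gamma ISIs
#'
#' The renewal-density series
#' `F(t) = exp(-alpha r t)/t * sum_m (alpha r t)^(m alpha) / Gamma(m alpha)`,
#' evaluated in log space term by term until the relative tail is below
#' `tol`. Provides an independent check on the grid solver.
#'
#' @param t times in s (> 0)
#' @param model a [gamma_isi()] model
#' @param tol relative series tolerance
#' @return rate values in Hz
#' @export
gamma_F_series <- function(t, model, tol = 1e-12) {
  stopifnot(inherits(model, "gamma_isi"), all(t > 0))
  a <- model$shape
  x <- a * model$rate * t  # alpha r t
  s <- numeric(length(t))
  lx <- log(x)
  m <- 0
  repeat {
    m <- m + 1
    term <- exp(m * a * lx - lgamma(m * a))
    s <- s + term
    if (m * a > max(x) && all(term <= tol * s)) break
    if (m > 10000) stop("F series failed to converge")
  }
  exp(-x) * s / t
}

#' Series solution for G'(t) - G(t) with gamma ISIs
#'
#' `D(t) = exp(-(alpha r + lambda) t)/(q t) *
#'   sum_m q^m (alpha r t)^(m alpha)/Gamma(m alpha)`; at `p = 1` the series
#' degenerates to its first term
#' `exp(-(alpha r + lambda) t) (alpha r t)^alpha / (t Gamma(alpha))`.
#'
#' @inheritParams gamma_F_series
#' @param syn a [synapse()] object
#' @return rate values in Hz
#' @export
gamma_Gdiff_series <- function(t, model, syn, tol = 1e-12) {
  stopifnot(inherits(model, "gamma_isi"), all(t > 0))
  a <- model$shape
  q <- syn$q
  x <- a * model$rate * t
  lx <- log(x)
  pref <- exp(-(x + syn$lambda * t))
  if (q == 0) {
    return(pref * exp(a * lx - lgamma(a)) / t)
  }
  s <- numeric(length(t))
  m <- 0
  repeat {
    m <- m + 1
    term <- exp(m * (a * lx + log(q)) - lgamma(m * a))
    s <- s + term
    if (m * a > max(x) && all(term <= tol * s)) break
    if (m > 10000) stop("G'-G series failed to converge")
  }
  pref * s / (q * t)
}

#' Laplace-domain kernels
#'
#' Closed forms of the kernel transforms in terms of the ISI transform `L`:
#' `L_F = L(z)/(1 - L(z))`,
#' `L_G = (L(z) - L(z+lambda)) / ((1 - L(z))(1 - q L(z+lambda)))`,
#' `L_{G'-G} = L(z+lambda)/(1 - q L(z+lambda))`, and
#' `L_{G'} = L_G + L_{G'-G}`.
#' Because `F` and `G` tend to non-zero constants, their transforms diverge
#' at `z = 0`; real arguments must be positive (complex arguments are allowed
#' for spectra).
#'
#' @param z transform argument(s): real > 0, or complex
#' @param isi an `isi_model`
#' @param syn a [synapse()] object (not needed for `which = "F"`)
#' @param which one of `"F"`, `"G"`, `"Gprime"`, `"Gdiff"`
#' @return transform values
#' @export
kernel_laplace <- function(z, isi, syn = NULL,
                           which = c("F", "G", "Gprime", "Gdiff")) {
  which <- match.arg(which)
  if (!is.complex(z) && any(z <= 0)) {
    stop("kernel transforms require z > 0 (they diverge at z = 0); ",
         "use kernel_grid_laplace() with a tail correction instead")
  }
  L <- isi_laplace(isi, z)
  if (which == "F") return(L / (1 - L))
  stopifnot(inherits(syn, "synapse_params"))
  Lh <- isi_laplace(isi, z + syn$lambda)
  G <- (L - Lh) / ((1 - L) * (1 - syn$q * Lh))
  D <- Lh / (1 - syn$q * Lh)
  switch(which, G = G, Gdiff = D, Gprime = G + D)
}

#' Numerical Laplace transform of a kernel grid
#'
#' Transforms a solved kernel grid: exact transforms of any peeled analytic
#' gamma components (truncated at `tmax`), trapezoid quadrature of the smooth
#' remainder, and the analytic tail `asymptote * exp(-z tmax)/z` beyond the
#' horizon. Used to cross-check the closed forms of [kernel_laplace()].
#'
#' @param grid a `kernel_grid`
#' @param z real argument(s) > 0
#' @return transform values
#' @export
kernel_grid_laplace <- function(grid, z) {
  stopifnot(inherits(grid, "kernel_grid"), all(z > 0))
  tt <- c(0, grid$t)
  rem <- if (is.null(grid$remainder)) grid$values else grid$remainder
  y0 <- c(grid$x0, rem)
  vapply(z, function(zz) {
    v <- 0
    if (!is.null(grid$analytic)) {
      an <- grid$analytic
      v <- v + sum(an$weight * (an$rate / (an$rate + zz))^an$shape *
                     pgamma(grid$tmax, an$shape, rate = an$rate + zz))
    }
    y <- y0 * exp(-zz * tt)
    v <- v + sum((y[-1] + y[-length(y)]) / 2) * grid$dt
    v + grid$asymptote * exp(-zz * grid$tmax) / zz
  }, numeric(1))
}

# ---- covariances and spectra ------------------------------------------------

# A covariance function is stored as delta_weight * delta(t) plus a
# continuous part decomposed as
#   sum_i weight_i dgamma(t; shape_i, rate_i) + remainder(t) + const,
# where the gamma components carry any integrable singularity at t = 0
# (bursty shapes alpha < 1) exactly and the remainder is smooth. `values`
# holds the total continuous part on the grid for plotting/inspection.
new_covariance_function <- function(delta_weight, t, values, dt, tmax, kind,
                                    analytic = NULL, remainder = NULL,
                                    const = 0) {
  if (is.null(remainder)) remainder <- values - const
  structure(list(delta_weight = delta_weight, t = t, values = values,
                 dt = dt, tmax = tmax, kind = kind, analytic = analytic,
                 remainder = remainder, const = const),
            class = "covariance_function")
}

# triangular-window average (1/b) int (1 - |u - c|/b) dgamma(u; s, r) du,
# exact via incomplete-gamma first moments; window clipped at u = 0
tri_avg_gamma <- function(s, r, c, b) {
  m0 <- function(a1, a2) pgamma(a2, s, rate = r) - pgamma(a1, s, rate = r)
  m1 <- function(a1, a2) {
    (s / r) * (pgamma(a2, s + 1, rate = r) - pgamma(a1, s + 1, rate = r))
  }
  lo <- max(0, c - b)
  left <- (1 - c / b) * m0(lo, c) + m1(lo, c) / b
  right <- (1 + c / b) * m0(c, c + b) - m1(c, c + b) / b
  (left + right) / b
}

#' @export
print.covariance_function <- function(x, ...) {
  cat(sprintf("<%s covariance> delta weight %.6g Hz; continuous part on ",
              x$kind, x$delta_weight),
      sprintf("(0, %g] s (%.4g Hz^2 at first lag)\n", x$tmax, x$values[1]))
  invisible(x)
}

#' Evaluate a covariance function at arbitrary lags
#'
#' `covariance_at()` interpolates the continuous part at `|lag|` (the
#' function is even in time); the Dirac component at zero lag is carried
#' separately in `$delta_weight` and is not included. Note the continuous
#' part can have an integrable singularity at zero lag for bursty drive.
#'
#' `covariance_bin_average()` returns what a binned covariance estimator
#' measures at lag `l = k * bin`: the triangular-window average
#' `(1/bin) int (1 - |u - l|/bin) cov(u) du`, using the exact
#' incomplete-gamma integrals of the analytic components (so zero-lag bins
#' are correct even when the continuous part diverges at 0) plus a weighted
#' trapezoid over the smooth remainder. The Dirac component contributes
#' `delta_weight / bin` to the zero-lag bin only.
#'
#' @param covf a `covariance_function`
#' @param lag lag(s) in s
#' @return continuous-part values in Hz^2
#' @export
covariance_at <- function(covf, lag) {
  al <- abs(lag)
  if (any(al > covf$tmax)) stop("lag beyond covariance horizon")
  # value at lag 0+ extrapolated from the first grid point
  approx(c(0, covf$t), c(covf$values[1], covf$values), xout = al)$y
}

#' @rdname covariance_at
#' @param bin bin width in s (`lag` should be a multiple of it)
#' @param include_delta add `delta_weight / bin` to the zero-lag value
#' @export
covariance_bin_average <- function(covf, lag, bin, include_delta = TRUE) {
  vapply(lag, function(lg) {
    lg <- abs(lg)
    if (lg + bin > covf$tmax) stop("lag + bin beyond covariance horizon")
    v <- covf$const
    if (!is.null(covf$analytic)) {
      an <- covf$analytic
      for (i in seq_len(nrow(an))) {
        contrib <- tri_avg_gamma(an$shape[i], an$rate[i], lg, bin)
        if (lg == 0) contrib <- 2 * contrib  # even continuation of cov(|u|)
        v <- v + an$weight[i] * contrib
      }
    }
    # triangular-weighted trapezoid of the smooth remainder
    lo <- max(0, lg - bin)
    hi <- lg + bin
    n <- max(80L, 2L * ceiling((hi - lo) / covf$dt))
    u <- seq(lo, hi, length.out = n + 1)
    h <- (hi - lo) / n
    w <- pmax(0, 1 - abs(u - lg) / bin)
    if (lg == 0) w <- 2 * w  # even continuation folded onto u >= 0
    y <- approx(c(0, covf$t), c(covf$remainder[1], covf$remainder),
                xout = u)$y
    wy <- w * y
    v <- v + (sum(wy) - (wy[1] + wy[n + 1]) / 2) * h / bin
    if (include_delta && lg == 0) v <- v + covf$delta_weight / bin
    v
  }, numeric(1))
}

#' Autocovariance of the release train from one site
#'
#' `AutoCov(chi)(t) = <chi> delta(t) + p <chi> (G(|t|) - r <x>_inf)` with
#' `<chi> = p r <x>_inf`. The Dirac weight is stored separately
#' (`delta_weight`); the continuous part is negative at short lags for every
#' renewal model - the signature of depression.
#'
#' @inheritParams solve_release_triggered_rate
#' @param G_grid optional precomputed `G` kernel grid
#' @return a `covariance_function`
#' @export
release_autocovariance <- function(isi, syn, dt = 5e-4, tmax = NULL,
                                   moments = NULL, G_grid = NULL) {
  if (is.null(G_grid)) {
    G_grid <- solve_release_triggered_rate(isi, syn, dt, tmax,
                                           moments = moments)
  }
  r <- isi_rate(isi)
  x_inf <- prespike_occupancy_mean(isi, syn)
  chi <- syn$p * r * x_inf
  sc <- syn$p * chi
  vals <- sc * (G_grid$values - r * x_inf)
  analytic <- if (!is.null(G_grid$analytic)) {
    transform(G_grid$analytic, weight = weight * sc)
  } else NULL
  rem <- if (is.null(G_grid$remainder)) G_grid$values else G_grid$remainder
  new_covariance_function(chi, G_grid$t, vals, G_grid$dt, G_grid$tmax,
                          kind = "release auto", analytic = analytic,
                          remainder = sc * rem, const = -sc * r * x_inf)
}

#' Cross-covariance of release trains from two sites sharing a neuron
#'
#' `CrossCov(chi_x, chi_z)(t) = p^2 r <xz>_inf [delta(t) +
#'   (<x>_inf/<xz>_inf)(G(|t|) - r <x>_inf) + q (G'(|t|) - G(|t|))]`.
#'
#' @inheritParams release_autocovariance
#' @param D_grid optional precomputed `G' - G` kernel grid
#' @return a `covariance_function`
#' @export
release_crosscovariance <- function(isi, syn, dt = 5e-4, tmax = NULL,
                                    moments = NULL, G_grid = NULL,
                                    D_grid = NULL) {
  if (is.null(G_grid)) {
    G_grid <- solve_release_triggered_rate(isi, syn, dt, tmax,
                                           moments = moments)
  }
  if (is.null(D_grid)) {
    D_grid <- solve_release_rate_difference(isi, syn, dt, tmax,
                                            moments = moments)
  }
  r <- isi_rate(isi)
  x_inf <- prespike_occupancy_mean(isi, syn)
  xz <- joint_prespike_occupancy(isi, syn)
  w <- syn$p^2 * r * xz
  cG <- w * x_inf / xz
  cD <- w * syn$q
  vals <- cG * (G_grid$values - r * x_inf) + cD * D_grid$values
  an <- NULL
  if (!is.null(G_grid$analytic)) {
    an <- rbind(an, transform(G_grid$analytic, weight = weight * cG))
  }
  if (!is.null(D_grid$analytic)) {
    an <- rbind(an, transform(D_grid$analytic, weight = weight * cD))
  }
  remG <- if (is.null(G_grid$remainder)) G_grid$values else G_grid$remainder
  remD <- if (is.null(D_grid$remainder)) D_grid$values else D_grid$remainder
  new_covariance_function(w, G_grid$t, vals, G_grid$dt, G_grid$tmax,
                          kind = "release cross", analytic = an,
                          remainder = cG * remG + cD * remD,
                          const = -cG * r * x_inf)
}

new_spectrum_grid <- function(omega, S, kind) {
  if (any(!is.finite(S))) stop("spectrum contains non-finite values")
  structure(list(omega = omega, S = S, kind = kind), class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<%s power spectrum> %d frequencies on [%.3g, %.3g] rad/s\n",
              x$kind, length(x$omega), min(x$omega), max(x$omega)))
  invisible(x)
}

#' Power spectrum of the presynaptic spike train
#'
#' `S(omega) = r (1 + 2 Re L_F(i omega))` for `omega > 0`; the
#' `r pi delta(omega)` zero-frequency component is excluded (ask for
#' `omega = 0` and you get an error pointing here). Flat at `r` for Poisson
#' trains and in the high-frequency limit.
#'
#' @param omega angular frequencies in rad/s (> 0)
#' @param isi an `isi_model`
#' @return a `spectrum_grid` (units Hz)
#' @export
spike_power_spectrum <- function(omega, isi) {
  if (any(omega <= 0)) {
    stop("omega must be > 0: the zero-frequency delta component ",
         "(r * pi * delta(omega)) is carried separately and excluded ",
         "from the spectrum grid")
  }
  r <- isi_rate(isi)
  LF <- kernel_laplace(1i * omega, isi, which = "F")
  new_spectrum_grid(omega, r * (1 + 2 * Re(LF)), "spike")
}

#' Power spectrum of the release train
#'
#' `S(omega) = <chi> (1 + 2 p Re L_G(i omega))` with
#' `<chi> = p r <x>_inf`; the `<chi>^2 ... delta(omega)` component is again
#' excluded. Tends to `<chi>` at high frequency.
#'
#' @inheritParams spike_power_spectrum
#' @param syn a [synapse()] object
#' @return a `spectrum_grid` (units Hz)
#' @export
release_power_spectrum <- function(omega, isi, syn) {
  if (any(omega <= 0)) {
    stop("omega must be > 0; the zero-frequency delta component is ",
         "excluded from the spectrum grid")
  }
  r <- isi_rate(isi)
  x_inf <- prespike_occupancy_mean(isi, syn)
  chi <- syn$p * r * x_inf
  LG <- kernel_laplace(1i * omega, isi, syn, which = "G")
  new_spectrum_grid(omega, chi * (1 + 2 * syn$p * Re(LG)), "release")
}

#' Write kernel, covariance or spectrum grids to CSV
#'
#' Kernels: columns `t_s, value_hz`; covariances: `t_s, continuous_hz2` with
#' the Dirac weight recorded on a header comment line; spectra:
#' `omega_rad_s, S_hz`.
#'
#' @param x a `kernel_grid`, `covariance_function` or `spectrum_grid`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_grid_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(packageVersion("depressr"))
  if (inherits(x, "kernel_grid")) {
    writeLines(sprintf("# depressr %s kernel %s; asymptote_hz=%.12g",
                       ver, x$kind, x$asymptote), con)
    utils::write.csv(data.frame(t_s = x$t, value_hz = x$values),
                     con, row.names = FALSE)
  } else if (inherits(x, "covariance_function")) {
    writeLines(sprintf("# depressr %s %s covariance; delta_weight_hz=%.12g",
                       ver, x$kind, x$delta_weight), con)
    utils::write.csv(data.frame(t_s = x$t, continuous_hz2 = x$values),
                     con, row.names = FALSE)
  } else if (inherits(x, "spectrum_grid")) {
    writeLines(sprintf("# depressr %s %s power spectrum", ver, x$kind), con)
    utils::write.csv(data.frame(omega_rad_s = x$omega, S_hz = x$S),
                     con, row.names = FALSE)
  } else {
    stop("unsupported object")
  }
  invisible(path)
}
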