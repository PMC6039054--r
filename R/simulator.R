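#' Event-driven Monte-Carlo simulation of depressing synaptic transmission
#'
#' Realises the full stochastic model without time discretisation of the
#' synapse: for every presynaptic neuron a renewal spike train is sampled
#' (directly for gamma ISIs, by SDE simulation for integrate-and-fire
#' models); at each spike an empty site restocks with the exact probability
#' `1 - exp(-lambda * gap)` and a stocked site releases with probability `p`.
#' Under one master seed, neuron `i` draws its spikes from substream `2i` and
#' its site randomness from substream `2i + 1`, so realisations are
#' reproducible and independent across neurons regardless of `N` and `n`.
#'
#' A burn-in of `max(10/lambda, 10/r)` seconds is recorded in the result and
#' discarded by all estimators.
#'
#' @param isi an `isi_model`
#' @param syn a [synapse()] object
#' @param conn a [connectivity()] spec (`N` neurons x `n` sites)
#' @param n_spikes spikes per neuron (alternative to `duration`)
#' @param duration post-burn-in simulated time in s (alternative to
#'   `n_spikes`)
#' @param seed integer master seed
#' @param dt Euler step in s for integrate-and-fire spike sampling
#' @return object of class `sim_result` with per-neuron spike times,
#'   per-site pre-spike occupancies and release indicators
#' @export
simulate_transmission <- function(isi, syn, conn = connectivity(N = 1, n = 1),
                                  n_spikes = NULL, duration = NULL, seed,
                                  dt = 1e-5) {
  stopifnot(xor(is.null(n_spikes), is.null(duration)))
  r <- isi_rate(isi)
  burn <- max(10 / syn$lambda, 10 / r)
  spikes <- vector("list", conn$N)
  occ <- vector("list", conn$N)
  rel <- vector("list", conn$N)
  t_end <- Inf
  for (i in seq_len(conn$N)) {
    if (!is.null(n_spikes)) {
      gaps <- sample_isis(isi, n_spikes, seed, stream = 2 * i, dt = dt)
    } else {
      need <- burn + duration
      target <- ceiling(need * r * 1.05 + 6 * sqrt(need * r) + 50)
      gaps <- sample_isis(isi, target, seed, stream = 2 * i, dt = dt)
      chunk <- 0
      while (sum(gaps) < need) {
        chunk <- chunk + 1
        extra <- sample_isis(isi, max(100, ceiling(0.1 * target)), seed,
                             stream = 2 * i + (2 * conn$N + 2) * chunk,
                             dt = dt)
        gaps <- c(gaps, extra)
      }
      gaps <- gaps[seq_len(which(cumsum(gaps) >= need)[1])]
    }
    st <- cpp_site_release(gaps, syn$p, syn$lambda, conn$n, seed,
                           2 * i + 1)
    spikes[[i]] <- cumsum(gaps)
    occ[[i]] <- st$occ_pre
    rel[[i]] <- st$release
  }
  if (!is.null(duration)) {
    t_end <- burn + duration
  } else {
    t_end <- min(vapply(spikes, function(s) s[length(s)], numeric(1)))
  }
  structure(list(spikes = spikes, occ_pre = occ, release = rel,
                 burn = burn, t_end = t_end, seed = seed,
                 isi = isi, syn = syn, conn = conn, dt = dt),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  ns <- sum(vapply(x$spikes, length, numeric(1)))
  cat(sprintf(
    "<simulation> %d neurons x %d sites, %d spikes, burn-in %g s, seed %d\n",
    x$conn$N, x$conn$n, ns, x$burn, x$seed))
  invisible(x)
}

#' Release times of one site
#'
#' @param sim a `sim_result`
#' @param neuron,site indices
#' @param after drop events at or before this time (defaults to the burn-in)
#' @return event-time vector in s
#' @export
site_release_train <- function(sim, neuron = 1, site = 1, after = sim$burn) {
  s <- sim$spikes[[neuron]]
  s[sim$release[[neuron]][, site] == 1 & s > after & s <= sim$t_end]
}

#' Pooled release times across all sites
#'
#' @inheritParams site_release_train
#' @return sorted event-time vector in s
#' @export
pooled_release_times <- function(sim, after = 0) {
  out <- vector("list", sim$conn$N)
  for (i in seq_len(sim$conn$N)) {
    s <- sim$spikes[[i]]
    reps <- rowSums(sim$release[[i]])
    keep <- reps > 0 & s <= sim$t_end
    out[[i]] <- rep(s[keep], reps[keep])
  }
  tt <- sort(unlist(out))
  tt[tt > after]
}

#' Occupancy statistics from a simulation
#'
#' Estimates the pre-spike mean occupancy `x_inf` (pre-spike snapshots), the
#' time-averaged occupancy `x_bar` and the shared-train joint pre-spike mean
#' `xz_inf` (first two sites of each neuron), with batch-means standard
#' errors. The time average uses the conditional expectation of the occupied
#' fraction of each inter-spike gap given its endpoint states (exact for the
#' exponential restock process), which removes the need to store restock
#' times.
#'
#' @param sim a `sim_result` with at least `min_spikes` post-burn-in spikes
#' @param batches number of batches for the standard errors
#' @param min_spikes required pooled spike count
#' @return list with `x_inf`, `x_bar`, `xz_inf` and their `*_se`, plus the
#'   pooled spike count `n_spikes`
#' @export
estimate_occupancy_stats <- function(sim, batches = 20, min_spikes = 1e4) {
  lam <- sim$syn$lambda
  occ_all <- list(); prod_all <- list()
  frac_all <- list(); w_all <- list()
  for (i in seq_len(sim$conn$N)) {
    s <- sim$spikes[[i]]
    keep <- s > sim$burn & s <= sim$t_end
    if (sum(keep) < 2) next
    oc <- sim$occ_pre[[i]][keep, , drop = FALSE]
    re <- sim$release[[i]][keep, , drop = FALSE]
    occ_all[[i]] <- as.numeric(oc)
    if (sim$conn$n >= 2) prod_all[[i]] <- oc[, 1] * oc[, 2]
    # conditional occupied fraction per gap, per site
    tk <- s[keep]
    gaps <- diff(tk)
    post <- oc - re                      # state just after each spike
    m <- length(tk)
    eg <- exp(-lam * gaps)
    cond <- (1 / lam - gaps * eg / (1 - eg)) / gaps  # E[T | T < gap]/gap
    fr <- matrix(0, m - 1, sim$conn$n)
    for (j in seq_len(sim$conn$n)) {
      s0 <- post[-m, j]
      e1 <- oc[-1, j]
      fr[, j] <- ifelse(s0 == 1, 1, ifelse(e1 == 1, 1 - cond, 0))
    }
    frac_all[[i]] <- as.numeric(fr * gaps)   # occupied time per gap
    w_all[[i]] <- rep(gaps, sim$conn$n)
  }
  ov <- unlist(occ_all)
  if (length(ov) < min_spikes) {
    stop("too few post-burn-in spikes (", length(ov), ") for estimation")
  }
  batch_stat <- function(x, w = NULL) {
    idx <- cut(seq_along(x), batches, labels = FALSE)
    if (is.null(w)) {
      bm <- tapply(x, idx, mean)
    } else {
      bm <- tapply(x, idx, sum) / tapply(w, idx, sum)
    }
    c(mean = if (is.null(w)) mean(x) else sum(x) / sum(w),
      se = sd(bm) / sqrt(length(bm)))
  }
  xi <- batch_stat(ov)
  ft <- unlist(frac_all)
  wt <- unlist(w_all)
  xb <- batch_stat(ft, wt)
  out <- list(x_inf = unname(xi["mean"]), x_inf_se = unname(xi["se"]),
              x_bar = unname(xb["mean"]), x_bar_se = unname(xb["se"]),
              n_spikes = length(ov) / sim$conn$n)
  if (sim$conn$n >= 2) {
    pv <- unlist(prod_all)
    xz <- batch_stat(pv)
    out$xz_inf <- unname(xz["mean"])
    out$xz_inf_se <- unname(xz["se"])
  }
  out
}

bin_counts <- function(times, t0, t1, bin) {
  nb <- floor((t1 - t0) / bin)
  tt <- times[times > t0 & times <= t0 + nb * bin]
  tabulate(pmin(nb, floor((tt - t0) / bin) + 1L), nbins = nb)
}

#' Binned covariance of event trains
#'
#' Empirical auto- or cross-covariance of event counts in bins of width
#' `bin`, in Hz^2, averaged over the supplied realisations with across-
#' realisation standard errors. For `"auto"`, `trains` is a list of
#' independent event-time vectors (a single train is split into 20
#' segments); the zero-lag bin contains the Dirac component as
#' `delta_weight / bin` plus the continuous part. For `"cross"`, `trains` is
#' a list of pairs (2-element lists); positive- and negative-lag estimates
#' are averaged since the cross-covariance of statistically exchangeable
#' sites is even.
#'
#' @param trains list of event-time vectors, or of pairs for `"cross"`
#' @param pair_mode `"auto"` or `"cross"`
#' @param bin bin width in s
#' @param max_lag largest lag in s (must be >= `bin`)
#' @param t0,t1 time window analysed (events outside are dropped)
#' @return data.frame with `lag_s`, `cov_hz2`, `se_hz2`
#' @export
estimate_covariance <- function(trains, pair_mode = c("auto", "cross"),
                                bin = 0.005, max_lag = 0.25, t0 = 0,
                                t1 = NULL) {
  pair_mode <- match.arg(pair_mode)
  if (bin > max_lag) stop("bin must not exceed max_lag")
  if (pair_mode == "auto" && length(trains) == 1) {
    tr <- trains[[1]]
    if (is.null(t1)) t1 <- max(tr)
    edges <- seq(t0, t1, length.out = 21)
    trains <- lapply(1:20, function(k) tr[tr > edges[k] & tr <= edges[k + 1]])
    t0s <- edges[-21]; t1s <- edges[-1]
  } else {
    t0s <- rep(t0, length(trains))
    if (is.null(t1)) {
      t1 <- max(unlist(trains))
    }
    t1s <- rep(t1, length(trains))
  }
  L <- round(max_lag / bin)
  acc <- matrix(NA_real_, length(trains), L + 1)
  for (k in seq_along(trains)) {
    if (pair_mode == "auto") {
      c1 <- bin_counts(trains[[k]], t0s[k], t1s[k], bin)
      c2 <- c1
    } else {
      pr <- trains[[k]]
      c1 <- bin_counts(pr[[1]], t0s[k], t1s[k], bin)
      c2 <- bin_counts(pr[[2]], t0s[k], t1s[k], bin)
    }
    if (pair_mode == "auto") {
      a <- stats::acf(c1, lag.max = L, type = "covariance", plot = FALSE,
                      demean = TRUE)$acf[, 1, 1]
      acc[k, ] <- a / bin^2
    } else {
      cc <- stats::ccf(c1, c2, lag.max = L, type = "covariance",
                       plot = FALSE)$acf[, 1, 1]
      # lags -L..L; the site pair is exchangeable, average the two sides
      acc[k, ] <- (cc[(L + 1):(2 * L + 1)] + cc[(L + 1):1]) / 2 / bin^2
    }
  }
  data.frame(lag_s = (0:L) * bin,
             cov_hz2 = colMeans(acc),
             se_hz2 = apply(acc, 2, sd) / sqrt(nrow(acc)))
}

#' Averaged periodogram of event trains
#'
#' Splits each train into windows of `window` seconds, bins events at `bin`,
#' subtracts the window mean (removing the zero-frequency delta) and averages
#' the periodograms `|FFT|^2 / T_window`, which converges to the point-
#' process power spectrum (units Hz). Standard errors are across windows.
#'
#' @param trains list of event-time vectors (independent realisations)
#' @param window window length in s
#' @param bin bin width in s
#' @param t0 drop events at or before this time
#' @return data.frame with `omega_rad_s`, `S_hz`, `se_hz`
#' @export
estimate_spectrum <- function(trains, window = 10, bin = 0.001, t0 = 0) {
  if (!is.list(trains)) trains <- list(trains)
  W <- round(window / bin)
  segs <- list()
  for (tr in trains) {
    tr <- tr[tr > t0]
    if (length(tr) == 0) next
    tr <- tr - t0
    n_seg <- floor(max(tr) / window)
    for (s in seq_len(n_seg)) {
      cnt <- bin_counts(tr, (s - 1) * window, s * window, bin)
      segs[[length(segs) + 1]] <- cnt
    }
  }
  if (length(segs) < 20) stop("need at least 20 windows; lengthen the train")
  half <- floor(W / 2)
  P <- matrix(NA_real_, length(segs), half)
  for (k in seq_along(segs)) {
    x <- segs[[k]] - mean(segs[[k]])
    X <- fft(x)
    P[k, ] <- (Mod(X[2:(half + 1)])^2) / (W * bin)
  }
  # no binning correction: for frequencies well below the bin Nyquist the
  # boxcar bias is < sinc^2(omega bin / 2), i.e. under 1% for
  # omega bin < 0.2; choose the bin accordingly
  data.frame(omega_rad_s = 2 * pi * (1:half) / (W * bin),
             S_hz = colMeans(P),
             se_hz = apply(P, 2, sd) / sqrt(nrow(P)))
}

#' Post-synaptic EIF neuron driven by the simulated release trains
#'
#' Integrates `tau dv/dt = mu - v + delta_T exp((v - v_T)/delta_T)` with an
#' instantaneous jump `a` per pooled release event (Euler step `dt`,
#' threshold `v_th`, reset `v_re`) and returns the firing rate measured after
#' the simulation's burn-in.
#'
#' @param sim a `sim_result`
#' @param post an [eif_isi()] model carrying the post-synaptic parameters
#'   (`mu` is the post-synaptic rest; `sigma` is ignored - the only drive is
#'   synaptic)
#' @param a quantal EPSP amplitude in mV
#' @param dt Euler step in s
#' @return list with `rate_hz`, `n_spikes`, `duration_s`
#' @export
simulate_postsynaptic_eif <- function(sim, post, a = 0.3, dt = 1e-5) {
  stopifnot(inherits(post, "eif_isi"))
  rel <- pooled_release_times(sim)
  res <- cpp_post_eif(rel, a, post$tau, post$mu, post$delta_T, post$v_T,
                      post$v_th, post$v_re, dt, sim$burn, sim$t_end)
  list(rate_hz = res[1] / res[2], n_spikes = res[1], duration_s = res[2])
}

#' Sampled post-synaptic voltage trace
#'
#' Exact integration of the delta-EPSP membrane equation between release
#' events (exponential relaxation to `mu`, jump `a` per event), sampled every
#' `ds` seconds after the burn-in.
#'
#' @param sim a `sim_result`
#' @param a quantal amplitude in mV
#' @param tau membrane time constant in s
#' @param mu resting potential in mV
#' @param ds sampling interval in s
#' @return numeric vector of voltage samples in mV
#' @export
voltage_trace <- function(sim, a = sim$conn$a, tau = sim$conn$tau,
                          mu = sim$conn$mu, ds = 0.001) {
  rel <- pooled_release_times(sim)
  cpp_voltage_samples(rel, a, tau, mu, sim$burn, sim$t_end, ds)
}
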