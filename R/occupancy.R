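#' Synapse parameters
#'
#' One quantal release site: a presynaptic spike releases the stocked vesicle
#' with probability `p` (the site then empties); empty sites are restocked at
#' the memoryless rate `lambda`. `q = 1 - p` is carried along for the
#' formulas.
#'
#' @param p release probability in `[0, 1]`
#' @param lambda restock rate in Hz (> 0)
#' @return object of class `synapse_params`
#' @examples
#' synapse()  # defaults p = 0.6, lambda = 2 Hz
#' @export
synapse <- function(p = 0.6, lambda = 2) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(lambda),
            length(lambda) == 1L)
  if (p < 0 || p > 1) stop("release probability p must lie in [0, 1]")
  if (lambda <= 0) stop("restock rate lambda must be > 0")
  structure(list(p = p, q = 1 - p, lambda = lambda),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf("<synapse> p = %g, lambda = %g Hz\n", x$p, x$lambda))
  invisible(x)
}

#' Pre-spike mean release-site occupancy
#'
#' Steady-state probability that the site is stocked immediately before a
#' presynaptic spike,
#' `<x>_inf = (1 - L(lambda)) / (1 - q L(lambda))`,
#' where `L` is the ISI Laplace transform. This is the quantity that sets the
#' mean release rate `<chi> = p r <x>_inf` and the post-synaptic mean.
#'
#' @param isi an `isi_model`
#' @param syn a [synapse()] object
#' @return probability in `[0, 1]`
#' @examples
#' prespike_occupancy_mean(gamma_isi(1, 5), synapse(0.6, 2))  # 0.4
#' @export
prespike_occupancy_mean <- function(isi, syn) {
  L <- isi_laplace(isi, syn$lambda)
  (1 - L) / (1 - syn$q * L)
}

#' Time-averaged release-site occupancy
#'
#' `<x> = 1 - p r (1 - L(lambda)) / (lambda (1 - q L(lambda)))`, linked to
#' the pre-spike mean by the steady-state balance between total restocking
#' and total release, `lambda (1 - <x>) = p r <x>_inf`.
#'
#' @inheritParams prespike_occupancy_mean
#' @return probability in `[0, 1]`
#' @export
time_avg_occupancy_mean <- function(isi, syn) {
  L <- isi_laplace(isi, syn$lambda)
  r <- isi_rate(isi)
  1 - syn$p * r * (1 - L) / (syn$lambda * (1 - syn$q * L))
}

#' Conditional pre-spike occupancy along a fixed spike train
#'
#' For a fixed pattern of spike times, the expected occupancy immediately
#' before each spike (averaged over release and restock randomness only)
#' obeys the recursion
#' `xbar_m = xbar_{m-1} q exp(-lambda D) + (1 - exp(-lambda D))`
#' with gap `D` between spikes `m-1` and `m`, starting from `xbar_1 = 1`.
#'
#' @param spikes event-time vector in s (strictly increasing)
#' @param syn a [synapse()] object
#' @return vector of pre-spike expectations, one per spike, each in (0, 1]
#' @export
conditional_occupancy_recursion <- function(spikes, syn) {
  spikes <- as.numeric(spikes)
  if (length(spikes) < 1) stop("need at least one spike")
  if (length(spikes) > 1 && any(diff(spikes) <= 0)) {
    stop("spike times must be strictly increasing")
  }
  out <- numeric(length(spikes))
  out[1] <- 1
  if (length(spikes) > 1) {
    e <- exp(-syn$lambda * diff(spikes))
    for (m in 2:length(spikes)) {
      out[m] <- out[m - 1] * syn$q * e[m - 1] + (1 - e[m - 1])
    }
  }
  out
}

#' Pre-spike occupancy for arbitrarily correlated spike trains
#'
#' The general series form
#' `<x>_inf = 1 - (p/q) sum_k q^k <exp(-lambda T_k)>`,
#' where `T_k` is the sum of the last `k` ISIs. It holds for any stationary
#' spike train; for a renewal process the expectations factorise,
#' `<exp(-lambda T_k)> = L(lambda)^k`, and the closed form of
#' [prespike_occupancy_mean()] is recovered.
#'
#' @param joint_expectations numeric vector of `<exp(-lambda T_k)>` for
#'   `k = 1, 2, ...` (values in (0, 1], non-increasing); the series is
#'   truncated once `q^k < 1e-12`, so supply at least that many terms or the
#'   tail is treated as zero
#' @param p release probability
#' @return probability in `[0, 1]`
#' @export
general_prespike_mean <- function(joint_expectations, p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  ex <- as.numeric(joint_expectations)
  if (any(ex < 0 | ex > 1)) stop("expectations must lie in [0, 1]")
  q <- 1 - p
  if (q == 0) {
    # series degenerates to its first term in the q -> 0 limit
    return(1 - ex[1])
  }
  kmax <- min(length(ex), ceiling(-12 * log(10) / log(q)) + 1)
  k <- seq_len(kmax)
  1 - (p / q) * sum(q^k * ex[k])
}

#' Joint pre-spike occupancy of two sites sharing a presynaptic neuron
#'
#' Steady-state expectation `<xz>_inf` of the product of the two binary
#' occupancies immediately before a shared spike:
#' `<xz>_inf = (2 q <x>_inf (L(lambda) - L(2 lambda)) +
#'   1 - 2 L(lambda) + L(2 lambda)) / (1 - q^2 L(2 lambda))`.
#'
#' @inheritParams prespike_occupancy_mean
#' @return probability, between `<x>_inf^2` and `<x>_inf`
#' @export
joint_prespike_occupancy <- function(isi, syn) {
  L1 <- isi_laplace(isi, syn$lambda)
  L2 <- isi_laplace(isi, 2 * syn$lambda)
  x_inf <- (1 - L1) / (1 - syn$q * L1)
  (2 * syn$q * x_inf * (L1 - L2) + (1 - 2 * L1 + L2)) /
    (1 - syn$q^2 * L2)
}

#' Covariance of the two shared-train site occupancies
#'
#' Closed form
#' `p^2 (L(2 lambda) - L(lambda)^2) /
#'  ((1 - q^2 L(2 lambda)) (1 - q L(lambda))^2)`,
#' equal to `<xz>_inf - <x>_inf^2`. Non-negative for every renewal model by
#' Jensen's inequality (`L(2 lambda) >= L(lambda)^2`).
#'
#' @inheritParams prespike_occupancy_mean
#' @return covariance (dimensionless)
#' @export
joint_occupancy_covariance <- function(isi, syn) {
  L1 <- isi_laplace(isi, syn$lambda)
  L2 <- isi_laplace(isi, 2 * syn$lambda)
  syn$p^2 * (L2 - L1^2) /
    ((1 - syn$q^2 * L2) * (1 - syn$q * L1)^2)
}

#' Partner-site stock probabilities after a release
#'
#' Probability that the partner site (same presynaptic neuron) is stocked,
#' respectively unstocked, immediately after the first site releases:
#' `(q <xz>_inf / <x>_inf, 1 - q <xz>_inf / <x>_inf)`. These weights combine
#' the stocked/unstocked conditional kernels in the release cross-covariance.
#'
#' @inheritParams prespike_occupancy_mean
#' @return named numeric vector `c(stocked =, unstocked =)`, summing to 1
#' @export
conditional_stock_probabilities <- function(isi, syn) {
  x_inf <- prespike_occupancy_mean(isi, syn)
  if (x_inf <= 0) {
    stop("pre-spike occupancy is zero; conditional probabilities undefined")
  }
  xz <- joint_prespike_occupancy(isi, syn)
  s <- syn$q * xz / x_inf
  c(stocked = s, unstocked = 1 - s)
}

#' Bursty and regular asymptotics of the occupancy
#'
#' Limiting forms of `<exp(-lambda t)>` and the occupancy means for gamma
#' ISIs. The bursty branch (`alpha -> 0`, valid when `lambda/(alpha r) > 1`):
#' `<e^{-lambda t}> ~ 1 - alpha log(lambda/(alpha r))`,
#' `<x>_inf ~ (alpha/p) log(lambda/(alpha r))`,
#' `<x> ~ 1 - (r/lambda) alpha log(lambda/(alpha r))`.
#' The regular branch (`alpha -> Inf`): `<e^{-lambda t}> ~ exp(-lambda/r)`,
#' with the occupancy means from the same closed forms.
#'
#' @param alpha gamma shape
#' @param r presynaptic rate in Hz
#' @param syn a [synapse()] object
#' @param branch `"bursty"` or `"regular"`
#' @return list with `exp_lambda_t`, `x_inf`, `x_bar`
#' @export
bursty_regular_asymptotics <- function(alpha, r, syn,
                                       branch = c("bursty", "regular")) {
  branch <- match.arg(branch)
  if (alpha <= 0) stop("alpha must be > 0")
  if (branch == "bursty") {
    if (syn$lambda / (alpha * r) <= 1) {
      stop("bursty asymptotics need lambda/(alpha r) > 1")
    }
    if (alpha >= 1) {
      warning("bursty asymptotics requested at alpha >= 1; ",
              "the expansion is only accurate for alpha << 1")
    }
    lg <- log(syn$lambda / (alpha * r))
    list(exp_lambda_t = 1 - alpha * lg,
         x_inf = (alpha / syn$p) * lg,
         x_bar = 1 - (r / syn$lambda) * alpha * lg)
  } else {
    if (alpha <= 1) {
      warning("regular asymptotics requested at alpha <= 1; ",
              "the expansion is only accurate for alpha >> 1")
    }
    E <- exp(-syn$lambda / r)
    q <- syn$q
    list(exp_lambda_t = E,
         x_inf = (1 - E) / (1 - q * E),
         x_bar = 1 - syn$p * r * (1 - E) / (syn$lambda * (1 - q * E)))
  }
}

#' Occupancy summary
#'
#' Bundles the closed-form occupancy statistics for one (ISI model, synapse)
#' pair: pre-spike and time-averaged means, their binary-variable variances
#' `m (1 - m)`, the joint pre-spike mean for a shared-train site pair and its
#' covariance. Serialise with [occupancy_summary_json()].
#'
#' @inheritParams prespike_occupancy_mean
#' @return object of class `occupancy_summary`
#' @export
occupancy_summary <- function(isi, syn) {
  x_inf <- prespike_occupancy_mean(isi, syn)
  x_bar <- time_avg_occupancy_mean(isi, syn)
  xz <- joint_prespike_occupancy(isi, syn)
  structure(list(
    x_inf = x_inf,
    x_bar = x_bar,
    var_inf = x_inf * (1 - x_inf),
    var_bar = x_bar * (1 - x_bar),
    xz_inf = xz,
    cov_xz = xz - x_inf^2,
    rate_hz = isi_rate(isi),
    release_rate_hz = syn$p * isi_rate(isi) * x_inf,
    params = list(p = syn$p, lambda_hz = syn$lambda, isi = unclass(isi))
  ), class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat("<occupancy summary>\n")
  cat(sprintf("  pre-spike mean <x>_inf  = %.6f (var %.6f)\n",
              x$x_inf, x$var_inf))
  cat(sprintf("  time-avg mean  <x>      = %.6f (var %.6f)\n",
              x$x_bar, x$var_bar))
  cat(sprintf("  joint <xz>_inf = %.6f, cov = %.6f\n", x$xz_inf, x$cov_xz))
  cat(sprintf("  release rate <chi> = %.6f Hz (presynaptic %.4g Hz)\n",
              x$release_rate_hz, x$rate_hz))
  invisible(x)
}

#' @rdname occupancy_summary
#' @param x an `occupancy_summary`
#' @param path optional file; if `NULL` the JSON string is returned
#' @export
occupancy_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "occupancy_summary"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
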