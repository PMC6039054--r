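# Shared fixtures: the reference synapse (p = 0.6, lambda = 2 Hz) and a
# 5 Hz presynaptic rate, plus small independent oracles used across files.

table1_synapse <- function() synapse(p = 0.6, lambda = 2)

# independent quadrature oracle for <exp(-z t)> over a gamma ISI density
# (split at t = 1 so the integrable t^(shape-1) endpoint is isolated)
gamma_laplace_quad <- function(z, shape, rate) {
  f <- function(t) dgamma(t, shape, rate = shape * rate) * exp(-z * t)
  integrate(f, 0, 1, rel.tol = 1e-10)$value +
    integrate(f, 1, Inf, rel.tol = 1e-10)$value
}

# brute-force enumeration of all release/restock histories for a fixed spike
# train: returns the exact expected pre-spike occupancy at each spike.
# State: probability the site is stocked just before the current spike.
# Enumerate paths explicitly (release yes/no, restock yes/no per gap).
brute_force_prespike <- function(times, p, lambda) {
  q <- 1 - p
  m <- length(times)
  out <- numeric(m)
  # paths: list of (prob, stocked_before_next)
  paths <- list(list(pr = 1, stocked = TRUE))
  for (k in seq_len(m)) {
    out[k] <- sum(vapply(paths, function(pp) pp$pr * pp$stocked, numeric(1)))
    if (k == m) break
    gap <- times[k + 1] - times[k]
    prs <- 1 - exp(-lambda * gap)
    nxt <- list()
    for (pp in paths) {
      if (pp$stocked) {
        # release (site empties, may restock) or not
        nxt[[length(nxt) + 1]] <- list(pr = pp$pr * p * prs, stocked = TRUE)
        nxt[[length(nxt) + 1]] <- list(pr = pp$pr * p * (1 - prs),
                                       stocked = FALSE)
        nxt[[length(nxt) + 1]] <- list(pr = pp$pr * q, stocked = TRUE)
      } else {
        nxt[[length(nxt) + 1]] <- list(pr = pp$pr * prs, stocked = TRUE)
        nxt[[length(nxt) + 1]] <- list(pr = pp$pr * (1 - prs),
                                       stocked = FALSE)
      }
    }
    paths <- nxt
  }
  out
}

# direct ratio-of-integrals evaluation of the LIF pre-spike occupancy (the
# occupancy formula written out in reduced coordinates), used as a second
# code path against the generic Laplace-based formula.
lif_occupancy_direct <- function(model, syn) {
  nu <- model$tau * syn$lambda
  y_th <- (model$v_th - model$mu) / model$sigma
  y_re <- (model$v_re - model$mu) / model$sigma
  ival <- function(w_re) {
    f1 <- function(u) {
      y <- exp(log(u) / nu)
      exp(-y^2 / 2) * (exp(y * y_th) - w_re * exp(y * y_re))
    }
    p1 <- integrate(f1, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value / nu
    f2 <- function(y) {
      y^(nu - 1) * (exp(y * y_th - y^2 / 2) - w_re * exp(y * y_re - y^2 / 2))
    }
    p2 <- integrate(f2, 1, Inf, rel.tol = 1e-12, abs.tol = 0)$value
    p1 + p2
  }
  ival(1) / ival(1 - syn$p)
}

# batch-means mean and standard error of a (possibly autocorrelated) series
batch_se <- function(x, batches = 20) {
  idx <- cut(seq_along(x), batches, labels = FALSE)
  bm <- tapply(x, idx, mean)
  list(mean = mean(x), se = sd(bm) / sqrt(batches))
}
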