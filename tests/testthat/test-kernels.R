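syn <- table1_synapse()
pois <- gamma_isi(1, 5)

test_that("Kummer 1F1 matches quadrature of its Euler integral", {
  # 1F1(b-a; b; -x) via int_0^1 u^(b-a-1)(1-u)^(a-1) e^{-x u} du / B(b-a, a)
  for (x in c(0.5, 2, 4)) {
    for (ab in list(c(0.4, 0.8), c(1, 3), c(4, 8))) {
      a <- ab[1]; b <- ab[2]
      oracle <- integrate(function(u) {
        u^(b - a - 1) * (1 - u)^(a - 1) * exp(-x * u)
      }, 0, 1, rel.tol = 1e-12)$value / beta(b - a, a)
      expect_lt(abs(kummer_1f1(b - a, b, -x) - oracle), 1e-10)
    }
  }
  expect_equal(kummer_1f1(2, 5, 0), 1)
})

test_that("spike-triggered rate: Poisson flat, alpha=2 closed form, asymptote", {
  Fg <- solve_spike_triggered_rate(pois, 5e-4, 2)
  expect_lt(max(abs(Fg$values - 5)), 1e-5)
  g2 <- gamma_isi(2, 5)
  F2 <- solve_spike_triggered_rate(g2, 2.5e-4, 2)
  expect_lt(max(abs(F2$values - 5 * (1 - exp(-20 * F2$t)))), 1e-6)
  expect_lt(abs(tail(F2$values, 1) - 5) / 5, 1e-3)
})

test_that("gamma renewal-rate series: special cases and grid equivalence", {
  expect_equal(gamma_F_series(c(0.01, 0.3, 1.7), pois), rep(5, 3),
               tolerance = 1e-12)
  expect_equal(gamma_F_series(0.1, gamma_isi(2, 5)), 5 * (1 - exp(-2)),
               tolerance = 1e-10)
  for (a in c(0.4, 1, 4)) {
    g <- gamma_isi(a, 5)
    Fg <- solve_spike_triggered_rate(g, 5e-4, 2)
    expect_lt(max(abs(Fg$values - gamma_F_series(Fg$t, g))), 1e-5)
  }
})

test_that("release-triggered rate G: Poisson closed form and limits", {
  Gg <- solve_release_triggered_rate(pois, syn, 5e-4, 2)
  expect_lt(max(abs(Gg$values - 2 * (1 - exp(-5 * Gg$t)))), 1e-5)
  expect_lt(Gg$values[1], 0.02)  # site just emptied: G(0+) -> 0
  expect_lt(abs(tail(Gg$values, 1) - 2) / 2, 1e-3)
})

test_that("kernel difference G'-G: closed form, series, integral identity", {
  Dg <- solve_release_rate_difference(pois, syn, 5e-4, 2)
  expect_lt(max(abs(Dg$values - 5 * exp(-5 * Dg$t))), 1e-5)
  expect_equal(gamma_Gdiff_series(c(0.1, 0.6), pois, syn),
               5 * exp(-5 * c(0.1, 0.6)), tolerance = 1e-10)
  for (a in c(0.4, 4)) {
    g <- gamma_isi(a, 5)
    Dg <- solve_release_rate_difference(g, syn, 5e-4, 2)
    expect_lt(max(abs(Dg$values - gamma_Gdiff_series(Dg$t, g, syn))), 1e-5)
    # integral of G'-G equals its transform at z -> 0: L(lam)/(1-q L(lam))
    # (long horizon: the z -> 0 integral keeps the full slow tail)
    Dl <- solve_release_rate_difference(g, syn, 5e-4, 6)
    L <- isi_laplace(g, syn$lambda)
    expect_lt(abs(kernel_grid_laplace(Dl, 1e-8) - L / (1 - syn$q * L)),
              1e-4)
  }
  # p = 1: series degenerates to its first term
  s1 <- synapse(1, 2)
  g04 <- gamma_isi(0.4, 5)
  tt <- c(0.05, 0.2)
  expect_equal(gamma_Gdiff_series(tt, g04, s1),
               exp(-(2 * tt + 2 * tt)) * (2 * tt)^0.4 / (tt * gamma(0.4)),
               tolerance = 1e-10)
})

test_that("Laplace-domain kernels: closed forms and instant-restock limit", {
  expect_equal(kernel_laplace(50, pois, syn, "G"), 10 / (50 * 55),
               tolerance = 1e-12)
  # lambda -> infinity: G -> F
  fast <- synapse(0.6, 1e7)
  for (z in c(5, 50)) {
    expect_lt(abs(kernel_laplace(z, pois, fast, "G") -
                    kernel_laplace(z, pois, which = "F")), 1e-5)
  }
  expect_error(kernel_laplace(0, pois, syn, "G"), "z > 0")
  expect_error(kernel_laplace(-3, pois, which = "F"), "z > 0")
})

test_that("grid transforms with tail correction match the closed forms", {
  for (a in c(0.4, 1, 4)) {
    g <- gamma_isi(a, 5)
    Fg <- solve_spike_triggered_rate(g, 2.5e-4, 2)
    Gg <- solve_release_triggered_rate(g, syn, 2.5e-4, 2, F_grid = Fg)
    Dg <- solve_release_rate_difference(g, syn, 2.5e-4, 2)
    for (z in c(10, 50, 100)) {
      expect_lt(abs(kernel_grid_laplace(Fg, z) /
                      kernel_laplace(z, g, which = "F") - 1), 1e-4)
      expect_lt(abs(kernel_grid_laplace(Gg, z) /
                      kernel_laplace(z, g, syn, "G") - 1), 1e-4)
      expect_lt(abs(kernel_grid_laplace(Dg, z) /
                      kernel_laplace(z, g, syn, "Gdiff") - 1), 1e-4)
    }
  }
})

test_that("solver refinement converges (dt halving)", {
  g <- gamma_isi(0.4, 5)
  F1 <- solve_spike_triggered_rate(g, 1e-3, 2)
  F2 <- solve_spike_triggered_rate(g, 5e-4, 2)
  s <- gamma_F_series(F1$t, g)
  e1 <- max(abs(F1$values - s))
  e2 <- max(abs(F2$values[seq(2, length(F2$values), 2)] - s))
  expect_lt(e2, e1)
  expect_lt(e2, 1e-5)
})

test_that("release autocovariance: Poisson closed form and depression sign", {
  ac <- release_autocovariance(pois, syn, 5e-4, 2)
  expect_equal(ac$delta_weight, 1.2, tolerance = 1e-12)
  expect_lt(max(abs(ac$values - (-1.44 * exp(-5 * ac$t)))), 1e-5)
  expect_lt(abs(tail(ac$values, 1)), 1e-3)
  # negative short-lag autocovariance for bursty, Poisson and regular drive
  for (a in c(0.4, 1, 4)) {
    aci <- release_autocovariance(gamma_isi(a, 5), syn, 5e-4, 2)
    expect_lt(aci$values[1], 0)
  }
})

test_that("release cross-covariance: structure and limits", {
  cc <- release_crosscovariance(pois, syn, 5e-4, 2)
  xz <- joint_prespike_occupancy(pois, syn)
  expect_equal(cc$delta_weight, 0.36 * 5 * xz, tolerance = 1e-12)
  expect_lt(abs(tail(cc$values, 1)), 1e-3)
  # p = 0: the weight vanishes (the kernels themselves converge slowly in
  # this degenerate no-release case, hence the suppressed horizon warning)
  cc0 <- suppressWarnings(release_crosscovariance(pois, synapse(0, 2),
                                                  5e-4, 2))
  expect_equal(cc0$delta_weight, 0)
  expect_lt(max(abs(cc0$values)), 1e-12)
  expect_error(covariance_at(cc, 5), "horizon")
  expect_equal(covariance_at(cc, -0.1), covariance_at(cc, 0.1))
})

test_that("spike spectrum: flat for Poisson, high-frequency limit, errors", {
  om <- 2 * pi * c(1, 5, 20, 100)
  sp <- spike_power_spectrum(om, pois)
  expect_lt(max(abs(sp$S - 5)), 1e-8)
  sp4 <- spike_power_spectrum(om, gamma_isi(4, 5))
  expect_lt(abs(tail(sp4$S, 1) - 5) / 5, 0.05)
  expect_error(spike_power_spectrum(c(0, 1), pois), "delta")
})

test_that("release spectrum: closed Poisson value, positivity, limit", {
  om <- 2 * pi * c(1, 5, 20, 200)
  rs <- release_power_spectrum(om, pois, syn)
  # L_G(i w) for exponential ISIs: r lambda / (i w (i w + lambda + p r))
  LG <- 10 / (1i * om * (1i * om + 5))
  expect_equal(rs$S, 1.2 * (1 + 2 * 0.6 * Re(LG)), tolerance = 1e-10)
  expect_lt(abs(tail(rs$S, 1) - 1.2) / 1.2, 0.01)
  for (a in c(0.4, 1, 4)) {
    omg <- exp(seq(log(0.1), log(1000), length.out = 60))
    expect_true(all(release_power_spectrum(omg, gamma_isi(a, 5), syn)$S >= 0))
  }
})

test_that("kernel grids for LIF models from empirical ISI moments", {
  m <- lif_for_rate(10, sigma = 1, v_th = 10, v_re = 0)
  isis <- sample_isis(m, 2e5, seed = 31)
  mom <- empirical_density_moments(isis, dt = 1e-3, tmax = 3, lambda = 2)
  Fg <- solve_spike_triggered_rate(m, 1e-3, 3, moments = mom)
  Gg <- solve_release_triggered_rate(m, syn, 1e-3, 3, moments = mom,
                                     F_grid = Fg)
  expect_lt(abs(tail(Fg$values, 1) - 10) / 10, 0.02)
  xinf <- prespike_occupancy_mean(m, syn)
  expect_lt(abs(tail(Gg$values, 1) - 10 * xinf) / (10 * xinf), 0.02)
  expect_lt(abs(kernel_grid_laplace(Gg, 10) /
                  kernel_laplace(10, m, syn, "G") - 1), 0.05)
  expect_error(solve_spike_triggered_rate(m, 1e-3, 3), "moments")
})

test_that("grid CSV writers carry units and the Dirac weight", {
  f <- tempfile(fileext = ".csv")
  ac <- release_autocovariance(pois, syn, 1e-3, 2)
  write_grid_csv(ac, f)
  hdr <- readLines(f, n = 2)
  expect_match(hdr[1], "delta_weight_hz=1.2")
  expect_match(hdr[2], "t_s")
  d <- utils::read.csv(f, comment.char = "#")
  expect_equal(d$continuous_hz2, ac$values, tolerance = 1e-6)
})
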