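syn <- table1_synapse()

test_that("pre-spike and time-averaged occupancy: closed forms and limits", {
  pois <- gamma_isi(1, 5)
  expect_equal(prespike_occupancy_mean(pois, syn), 0.4, tolerance = 1e-12)
  expect_equal(time_avg_occupancy_mean(pois, syn), 0.4, tolerance = 1e-12)
  # no release: always stocked in steady state
  off <- synapse(p = 0, lambda = 2)
  for (m in list(pois, gamma_isi(0.3, 7))) {
    expect_equal(prespike_occupancy_mean(m, off), 1)
    expect_equal(time_avg_occupancy_mean(m, off), 1)
  }
  # lambda -> 0: never restocked
  expect_lt(prespike_occupancy_mean(pois, synapse(0.6, 1e-9)), 1e-8)
})

test_that("balance between restocking and release holds exactly", {
  models <- c(lapply(c(0.2, 0.4, 1, 2, 4, 10), gamma_isi, rate = 5),
              list(lif_for_rate(10, sigma = 1.45, v_th = 10, v_re = 5),
                   eif_for_rate(10, sigma = 1.45, v_re_eif = 9)))
  for (m in models) {
    lhs <- syn$lambda * (1 - time_avg_occupancy_mean(m, syn))
    rhs <- syn$p * isi_rate(m) * prespike_occupancy_mean(m, syn)
    expect_lt(abs(lhs - rhs) / rhs, 1e-10)
  }
})

test_that("occupancy recursion along fixed trains, with enumeration oracle", {
  expect_equal(conditional_occupancy_recursion(0.3, syn), 1)
  x2 <- conditional_occupancy_recursion(c(0, 0.5), syn)[2]
  expect_equal(x2, 0.4 * exp(-1) + (1 - exp(-1)), tolerance = 1e-12)
  # exhaustive enumeration over all release/restock histories
  times <- c(0, 0.15, 0.4, 0.45, 1.1, 1.3)
  expect_equal(conditional_occupancy_recursion(times, syn),
               brute_force_prespike(times, syn$p, syn$lambda),
               tolerance = 1e-12)
  expect_error(conditional_occupancy_recursion(c(1, 0.5), syn), "increasing")
})

test_that("recursion tail averages to the renewal pre-spike mean", {
  m <- gamma_isi(0.7, 5)
  tails <- vapply(1:400, function(k) {
    tr <- sample_isi_train(m, 60, seed = 1000 + k)
    mean(conditional_occupancy_recursion(tr, syn)[41:60])
  }, numeric(1))
  se <- sd(tails) / sqrt(length(tails))
  expect_lt(abs(mean(tails) - prespike_occupancy_mean(m, syn)), 3 * se)
})

test_that("general correlated-train series reduces to the renewal form", {
  for (m in list(gamma_isi(0.4, 5), gamma_isi(3, 5))) {
    L <- isi_laplace(m, syn$lambda)
    ex <- L^(1:2000)
    expect_lt(abs(general_prespike_mean(ex, syn$p) -
                    prespike_occupancy_mean(m, syn)), 1e-10)
  }
  expect_equal(general_prespike_mean(numeric(2000), 0.6), 1)
  # p = 1 degenerates to the first term
  expect_equal(general_prespike_mean(c(0.3, 0.2, 0.1), 1), 1 - 0.3)
})

test_that("general series with empirical multi-ISI expectations", {
  m <- gamma_isi(0.6, 5)
  isis <- matrix(sample_isis(m, 1.2e5, seed = 77), nrow = 60)
  Tk <- apply(isis, 2, cumsum)  # T_k per column realisation
  # per-realisation series value, giving a proper standard error
  q <- syn$q
  s_j <- 1 - (syn$p / q) * colSums(q^(1:60) * exp(-syn$lambda * Tk))
  se <- sd(s_j) / sqrt(length(s_j))
  expect_lt(abs(mean(s_j) - prespike_occupancy_mean(m, syn)), 3 * se)
})

test_that("joint occupancy of a shared-train site pair", {
  pois <- gamma_isi(1, 5)
  expect_equal(joint_prespike_occupancy(pois, syn), 8 / 41,
               tolerance = 1e-12)  # 0.195122
  expect_equal(joint_occupancy_covariance(pois, syn), 8 / 41 - 0.16,
               tolerance = 1e-12)  # 0.0351220
  off <- synapse(0, 2)
  expect_equal(joint_prespike_occupancy(pois, off), 1)
  expect_equal(joint_occupancy_covariance(pois, off), 0)
  # two code paths agree; bounds and positivity across models
  for (m in c(lapply(c(0.2, 0.5, 1, 2, 10), gamma_isi, rate = 5),
              list(lif_for_rate(10, sigma = 1.45, v_th = 10, v_re = 5),
                   eif_for_rate(10, sigma = 1.45, v_re_eif = 9)))) {
    xz <- joint_prespike_occupancy(m, syn)
    xi <- prespike_occupancy_mean(m, syn)
    expect_lt(abs((xz - xi^2) - joint_occupancy_covariance(m, syn)), 1e-10)
    expect_gte(xz, xi^2)
    expect_lte(xz, xi)
  }
})

test_that("partner-site stock probabilities", {
  pois <- gamma_isi(1, 5)
  pr <- conditional_stock_probabilities(pois, syn)
  expect_equal(unname(pr["stocked"]), 0.4 * (8 / 41) / 0.4, tolerance = 1e-12)
  expect_equal(sum(pr), 1)
  pr1 <- conditional_stock_probabilities(pois, synapse(1, 2))
  expect_equal(unname(pr1), c(0, 1))
})

test_that("bursty and regular asymptotic branches", {
  r <- 5
  a <- bursty_regular_asymptotics(1e-3, r, syn, "bursty")
  exact <- prespike_occupancy_mean(gamma_isi(1e-3, r), syn)
  expect_lt(abs(a$x_inf - exact) / exact, 0.05)
  reg <- bursty_regular_asymptotics(100, r, syn, "regular")
  exact_e <- isi_laplace(gamma_isi(100, r), syn$lambda)
  expect_lt(abs(reg$exp_lambda_t - exact_e) / exact_e, 0.01)
  # extreme bursty limit: occupancy vanishes
  expect_lt(bursty_regular_asymptotics(1e-6, r, syn, "bursty")$x_inf, 1e-4)
  expect_error(bursty_regular_asymptotics(2, r, syn, "bursty"), "lambda")
  expect_warning(bursty_regular_asymptotics(1.5, 2, synapse(0.6, 10),
                                            "bursty"), "alpha")
})

test_that("occupancy means are monotone in burstiness and cross at alpha=1", {
  alphas <- c(0.2, 0.5, 1, 2, 5, 10)
  xi <- vapply(alphas, function(a) {
    prespike_occupancy_mean(gamma_isi(a, 5), syn)
  }, numeric(1))
  xb <- vapply(alphas, function(a) {
    time_avg_occupancy_mean(gamma_isi(a, 5), syn)
  }, numeric(1))
  expect_true(all(diff(xi) > 0))
  expect_true(all(diff(xb) < 0))
  expect_lt(abs(xi[alphas == 1] - xb[alphas == 1]), 1e-12)
  expect_true(all((xi > xb + 1e-10) == (alphas > 1)))
})

test_that("regular depleted regime: release probability tends to lambda/r", {
  m <- gamma_isi(50, 200)
  p_rel <- syn$p * prespike_occupancy_mean(m, syn)
  expect_lt(abs(p_rel - syn$lambda / 200) / (syn$lambda / 200), 0.05)
})

test_that("occupancy summary is consistent and serialises", {
  m <- gamma_isi(0.4, 5)
  s <- occupancy_summary(m, syn)
  expect_equal(s$var_inf, s$x_inf * (1 - s$x_inf))
  expect_equal(s$cov_xz, s$xz_inf - s$x_inf^2)
  js <- jsonlite::fromJSON(occupancy_summary_json(s))
  expect_equal(js$x_inf, s$x_inf, tolerance = 1e-12)
  expect_equal(js$params$lambda_hz, 2)
})
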