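test_that("synaptic conductance decays exponentially and jumps by g_bar/tau", {
  g <- synapse_decay_jump(0.4, dt = 6, tau_syn = 3)
  expect_equal(g, 0.4 * exp(-2))
  g1 <- synapse_decay_jump(0, dt = 0.1, n_spikes = 1, g_bar = 0.3,
                           tau_syn = 3)
  expect_equal(g1, 0.3 / 3 * 1, tolerance = 1e-12)
  # time integral of a unitary transient equals g_bar
  dt <- 0.01
  g <- 0.3 / 3
  total <- g * 3 * (1 - exp(-1e4 * dt / 3))  # analytic; and by summation:
  gs <- g * exp(-(0:1e4) * dt / 3)
  expect_equal(sum(gs) * dt, 0.3, tolerance = 0.01)
  expect_equal(total, 0.3, tolerance = 1e-6)
})

test_that("Poisson drive through the synapse has stationary mean g_bar*K*r", {
  set.seed(1)
  K <- 50; r_ms <- 0.01; g_bar <- 0.2; dt <- 0.1
  n <- 2e5
  spikes <- rpois(n, K * r_ms * dt)
  g <- 0
  acc <- 0
  for (i in seq_len(n)) {
    g <- synapse_decay_jump(g, dt, spikes[i], g_bar, tau_syn = 3)
    if (i > 1000) acc <- acc + g
  }
  expect_equal(acc / (n - 1000), g_bar * K * r_ms, tolerance = 0.02)
})

test_that("recurrent current interpolates conductance- and current-based", {
  sp1 <- synapse_params(rho = 1)
  expect_equal(recurrent_current(-60, g_E = 0.1, g_I = 0, sp1),
               -0.1 * (-60 - 0))
  sp0 <- synapse_params(rho = 0)
  expect_equal(recurrent_current(-60, g_E = 0.1, g_I = 0, sp0, V_L = -65),
               -0.1 * (-65 - 0))
  # at V = V_rev the rho-part of that synapse vanishes
  sp <- synapse_params(rho = 0.5, V_rev_I = -75)
  expect_equal(recurrent_current(-75, g_E = 0, g_I = 0.2, sp, V_L = -65),
               -0.2 * 0.5 * (-65 + 75))
})

test_that("OU noise preserves its stationary law and correlation time", {
  set.seed(2)
  tau <- 3; sigma <- 1 / sqrt(2 * tau); dt <- 0.5
  n <- 2e5
  eta <- numeric(n)
  eta[1] <- rnorm(1, 0, sigma)
  for (i in 2:n) eta[i] <- ou_step(eta[i - 1], dt, tau, sigma)
  expect_equal(mean(eta), 0, tolerance = 0.01)
  expect_equal(var(eta), sigma^2, tolerance = 0.03)
  lag <- 4L  # 2 ms
  rho_hat <- cor(eta[-(1:lag)], eta[seq_len(n - lag)])
  expect_equal(rho_hat, exp(-lag * dt / tau), tolerance = 0.05)
})

test_that("background conductance has the stated mean and stays nonnegative", {
  set.seed(3)
  bp <- background_params(g_bar_E = 0.012, R_b_E = 5)
  g <- background_conductance(2e5, dt = 0.5, bp, K = 100, population = "E")
  expect_true(all(g >= 0))
  expect_equal(mean(g), 0.012 * 100 * 5e-3, tolerance = 0.03)
  # zero rate: identically zero
  bp0 <- background_params(R_b_E = 0)
  expect_true(all(background_conductance(100, 0.5, bp0, 100) == 0))
})

test_that("feedforward rate follows the quenched tuned form", {
  dis <- draw_disorder(200, 200, seed = 8)
  ff <- feedforward_params(K_ff_E = 20, K_ff_I = 160)
  # contrast amplitude: R1(C) = R1 log10(C + 1)
  expect_equal(20 * log10(101), 40.0864, tolerance = 1e-4)
  # C = 0 removes all orientation dependence
  r0 <- feedforward_rate(0.3, dis, ff, K = 100, contrast = 0)
  r1 <- feedforward_rate(1.2, dis, ff, K = 100, contrast = 0)
  expect_equal(r0, r1)
  expect_true(all(r0 >= 0))
  # theta = Delta_i maximizes the drive of neuron i (z1 > 0)
  i <- 7
  th <- seq(0, pi - 1e-9, length.out = 181)
  ri <- vapply(th, function(t)
    feedforward_rate(t, dis, ff, K = 100)[i], numeric(1))
  expect_lt(abs(th[which.max(ri)] - dis$delta[i]), pi / 120)
  # mean over neurons ~ c_ff K (R0 + R1(C)); quenched part averages out
  rr <- feedforward_rate(0.5, dis, ff, K = 100)
  expect_equal(mean(rr[dis$population == "I"]), 160 * (2 + 40.0864),
               tolerance = 0.05)
})

test_that("quenched disorder is frozen and has the stated marginals", {
  d1 <- draw_disorder(3000, 3000, seed = 5)
  d2 <- draw_disorder(3000, 3000, seed = 5)
  expect_identical(d1, d2)
  expect_true(all(d1$z1 >= 0))
  expect_true(all(d1$delta >= 0 & d1$delta < pi))
  expect_equal(mean(d1$x), 0, tolerance = 0.05)
  expect_equal(sd(d1$x), 1, tolerance = 0.05)
  # Rayleigh(1): mean sqrt(pi/2), E[z^2] = 2
  expect_equal(mean(d1$z1), sqrt(pi / 2), tolerance = 0.03)
  expect_equal(mean(d1$z1^2), 2, tolerance = 0.06)
})

test_that("feedforward filtering relaxes exponentially with unit gain", {
  # constant rate, no noise: settles to g_ff_bar * R (rate in 1/ms)
  g <- feedforward_conductance(rep(1000, 2000), dt = 0.05, g_ff_bar = 0.2,
                               tau_syn = 3, g0 = 0)
  expect_equal(g[length(g)], 0.2 * 1, tolerance = 1e-6)
  # step response has time constant tau_syn
  n_tau <- round(3 / 0.05)
  expect_equal(g[n_tau], 0.2 * (1 - exp(-1)), tolerance = 0.02)
  # noise on: stationary variance grows with the rate
  set.seed(4)
  v_lo <- var(feedforward_conductance(rep(500, 4e4), 0.5, 0.2,
                                      noise = TRUE)[-(1:100)])
  set.seed(4)
  v_hi <- var(feedforward_conductance(rep(4000, 4e4), 0.5, 0.2,
                                      noise = TRUE)[-(1:100)])
  expect_gt(v_hi, 3 * v_lo)
})
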