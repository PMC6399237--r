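test_that("OSI has the stated closed forms and invariances", {
  th <- seq(0, pi, length.out = 5)[1:4]
  expect_equal(osi(rep(3, 4), th), 0)
  expect_equal(osi(c(1, 0, 0, 0), th), 1)
  # r(theta) = r0 + r1 cos 2(theta - theta0) on an equally spaced grid
  # has OSI r1 / (2 r0) (discrete orthogonality of the harmonics)
  r0 <- 4; r1 <- 1.5; th0 <- 0.7
  th8 <- seq(0, pi, length.out = 9)[1:8]
  curve <- r0 + r1 * cos(2 * (th8 - th0))
  expect_equal(osi(curve, th8), r1 / (2 * r0))
  # invariant under uniform rescaling and global rotation
  expect_equal(osi(5 * curve, th8), osi(curve, th8))
  rot <- 0.4
  curve_rot <- r0 + r1 * cos(2 * (th8 - th0 - rot))
  expect_equal(osi(curve_rot, th8), osi(curve, th8))
  # matrix input: one OSI per row
  m <- rbind(curve, rep(1, 8))
  expect_equal(unname(osi(m, th8)), c(r1 / (2 * r0), 0))
  # all-zero curve is undefined, not 0
  expect_warning(o <- osi(rep(0, 4), th), "undefined")
  expect_true(is.na(o))
})

test_that("Fano factor uses the plain-average variance convention", {
  expect_equal(fano_factor(c(1, 3)), 0.5)   # population variance 1, mean 2
  expect_equal(fano_factor(c(4, 4, 4, 4)), 0)
  expect_equal(fano_factor(c(1, 3), unbiased = TRUE), 1)
  expect_warning(f0 <- fano_factor(c(0, 0, 0)), "undefined")
  expect_true(is.na(f0))
  set.seed(10)
  counts <- matrix(rpois(3 * 100, 5), nrow = 3)
  expect_length(fano_factor(counts), 3)
  # Poisson counts: FF = 1 within asymptotic sampling error
  set.seed(11)
  expect_lt(abs(fano_factor(rpois(1e4, 5)) - 1), 3 * sqrt(2 / 1e4))
})

test_that("CV and CV2 have the stated arithmetic and bounds", {
  expect_equal(cv_isi(c(1, 3)), 0.5)
  expect_equal(cv_isi(rep(2.5, 10)), 0)
  expect_equal(cv2_isi(c(1, 3)), 1)        # 2|3-1|/(3+1)
  expect_equal(cv2_isi(rep(4, 6)), 0)
  set.seed(12)
  isis <- rexp(1e5)
  expect_equal(cv_isi(isis), 1, tolerance = 0.02)
  expect_lte(cv2_isi(isis), 2)
  # CV2 is blind to slow rate modulation while CV is inflated
  sl <- generate_train("rate-modulated", rate = 20, duration = 20000,
                       mod_depth = 0.6, mod_period = 2000)
  isis_m <- diff(sl$times[[1]])
  expect_gt(cv_isi(isis_m), 5 * cv2_isi(isis_m))
})

test_that("serial rank correlations capture ordering structure", {
  expect_equal(serial_rank_correlations(1:30, 1)[1], 1)
  # strictly alternating short/long (shorts increasing, longs decreasing:
  # rank pairs are perfectly anti-aligned up to the interleave offset)
  alt <- as.vector(rbind(1 + 0.001 * (1:15), 10 - 0.001 * (1:15)))
  expect_lt(serial_rank_correlations(alt, 1)[1], -0.95)
  set.seed(13)
  shuffled <- sample(rexp(2000))
  src <- serial_rank_correlations(shuffled, 5)
  expect_true(all(abs(src) < 3 / sqrt(2000)))
})

test_that("count variance identities link FF to CV and SRCs", {
  expect_equal(ff_from_cv_src(0.5), 0.25)              # renewal: CV^2
  expect_equal(ff_from_cv_src(0.5, numeric(0)), 0.25)
  expect_gt(ff_from_cv_src(1, c(0.2, 0.1)), 1)         # positive SRC raise FF
  expect_lt(ff_from_cv_src(1, c(-0.2)), 1)             # negative SRC lower FF
  expect_equal(ff_from_cv_src(1, c(0.2, 0.1)), 1 * (1 + 2 * 0.3))
})

test_that("autocorrelation of a Poisson train is flat at the asymptote", {
  tr <- generate_train("poisson", rate = 50, duration = 1e5, seed = 14)
  ac <- spike_autocorrelation(tr, max_lag = 100)
  r <- firing_rates(tr)
  expect_equal(ac$asymptote, r^2)
  # flat: per-lag pair counts ~ (r dt)^2 T / dt, relative SE ~ 6%; bound at
  # ~4 sigma for the max over 100 lags, ~5 sigma for the mean
  expect_lt(max(abs(ac$ac - ac$asymptote)) / ac$asymptote, 0.28)
  expect_lt(abs(mean(ac$ac) - ac$asymptote) / ac$asymptote, 0.03)
})

test_that("autocorrelation of a periodic train peaks at multiples of the period", {
  tr <- generate_train("periodic", duration = 30000, period = 25)
  ac <- spike_autocorrelation(tr, max_lag = 120)
  peaks <- which(ac$ac > 0.5 * max(ac$ac))
  expect_equal(peaks, seq(25, 120, by = 25))
})

test_that("population AC is the mean of per-neuron ACs", {
  t1 <- generate_train("poisson", 15, 5000, seed = 1)$times[[1]]
  t2 <- generate_train("poisson", 25, 5000, seed = 2)$times[[1]]
  both <- spike_data(list(t1, t2), "E", 5000)
  ac_pop <- spike_autocorrelation(both, max_lag = 50)
  ac1 <- spike_autocorrelation(list(t1), duration = 5000, max_lag = 50)
  ac2 <- spike_autocorrelation(list(t2), duration = 5000, max_lag = 50)
  expect_equal(ac_pop$ac, (ac1$ac + ac2$ac) / 2)
  expect_equal(ac_pop$asymptote, (ac1$asymptote + ac2$asymptote) / 2)
})

test_that("decorrelation time recovers a planted exponential decay", {
  for (tau0 in c(8, 25, 60)) {
    lag <- 1:300
    ac <- structure(list(lag = lag, ac = 100 + 40 * exp(-lag / tau0),
                         asymptote = 100, rate_mean = 10, n_neurons = 1,
                         normalization = "rate_squared"),
                    class = "ac_function")
    fit <- decorrelation_time(ac)
    expect_equal(fit$tau_dec, tau0, tolerance = 0.05)
  }
  # flat AC: undefined, signaled
  flat <- structure(list(lag = 1:100, ac = rep(100, 100), asymptote = 100,
                         rate_mean = 10, n_neurons = 1,
                         normalization = "rate_squared"),
                    class = "ac_function")
  expect_warning(fit <- decorrelation_time(flat), "undefined")
  expect_true(is.na(fit$tau_dec))
  # loglog variant returns a dimensionless slope magnitude
  ac_pl <- structure(list(lag = 1:200, ac = 100 + 50 * (1:200)^-1.3,
                          asymptote = 100, rate_mean = 10, n_neurons = 1,
                          normalization = "rate_squared"),
                     class = "ac_function")
  fit_ll <- decorrelation_time(ac_pl, method = "loglog", frac = 0.001)
  expect_equal(fit_ll$tau_dec, 1.3, tolerance = 0.05)
})

test_that("rate normalization view rescales the asymptote to the mean rate", {
  tr <- generate_train("poisson", rate = 20, duration = 20000, seed = 3)
  ac <- spike_autocorrelation(tr, max_lag = 50)
  acn <- ac_normalize_rate(ac)
  expect_equal(acn$normalization, "rate")
  expect_equal(acn$asymptote, ac$asymptote / ac$rate_mean)
  expect_error(ac_normalize_rate(acn))  # not idempotent by design
})

test_that("windowed counts partition a train", {
  tr <- c(0.5, 10.1, 10.2, 25, 99.9)
  expect_equal(windowed_counts(tr, 100, 10), c(1, 2, 1, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(sum(windowed_counts(tr, 100, 25)), 5)
})

test_that("stats summary aggregates per-neuron and population measures", {
  sd_mix <- spike_data(
    list(generate_train("poisson", 20, 10000, seed = 4)$times[[1]],
         generate_train("gamma-renewal", 20, 10000, seed = 5,
                        shape = 4)$times[[1]]),
    population = c("E", "I"), duration = 10000)
  s <- stats_summary(sd_mix, max_lag = 50)
  expect_s3_class(s, "stats_summary")
  expect_equal(nrow(s$per_neuron), 2)
  expect_equal(s$per_neuron$cv[1], 1, tolerance = 0.1)
  expect_equal(s$per_neuron$cv[2], 0.5, tolerance = 0.1)
  expect_named(s$ac, c("E", "I"))
  counts <- matrix(c(rpois(50, 10), rpois(50, 10)), nrow = 2, byrow = TRUE)
  s2 <- stats_summary(sd_mix, counts = counts, max_lag = 50)
  expect_true(all(is.finite(s2$per_neuron$ff)))
})

test_that("decorrelation time also fits a refractory trough from below", {
  lag <- 1:300
  for (tau0 in c(12, 40)) {
    ac <- structure(list(lag = lag, ac = 100 - 60 * exp(-lag / tau0),
                         asymptote = 100, rate_mean = 10, n_neurons = 1,
                         normalization = "rate_squared"),
                    class = "ac_function")
    fit <- decorrelation_time(ac)
    expect_equal(fit$tau_dec, tau0, tolerance = 0.05)
    expect_equal(fit$sign, -1)
  }
  # smoothing suppresses an oscillatory ripple on the decay
  ripple <- 100 + 50 * exp(-lag / 30) * (1 + 0.6 * cos(2 * pi * lag / 20))
  ac_r <- structure(list(lag = lag, ac = ripple, asymptote = 100,
                         rate_mean = 10, n_neurons = 1,
                         normalization = "rate_squared"),
                    class = "ac_function")
  fit_r <- decorrelation_time(ac_r, smooth = 21)
  expect_equal(fit_r$tau_dec, 30, tolerance = 0.15)
})
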