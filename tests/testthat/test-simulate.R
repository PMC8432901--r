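test_that("absorbing quiescent state: no events, legitimate idle", {
  p <- wc_params(w0 = 0.2, w_sum = 1, h = 0, N = 50)
  sim <- wc_gillespie(p, t_max = 100, seed = 1, record = c("series", "events"),
                      burn_in = 0, init = c(k = 0, l = 0))
  expect_true(sim$absorbed)
  expect_equal(nrow(sim$events$events), 0)
  expect_true(all(sim$series$k == 0))
  expect_equal(sim$moments$mean_rate, 0)
})

test_that("recorded series and event replay agree exactly", {
  p <- wc_params(w0 = 0.2, w_sum = 2, h = 0.01, N = 30)
  sim <- wc_gillespie(p, t_max = 500, seed = 2,
                      record = c("series", "events"), dt_sample = 1,
                      burn_in = 50)
  rs <- rate_series_from_events(sim$events, dt_sample = 1)
  n <- length(sim$series$k)
  expect_equal(rs$k[seq_len(n)], sim$series$k)
  expect_equal(rs$l[seq_len(n)], sim$series$l)
  expect_equal(rs$R[seq_len(n)], sim$series$R)
})

test_that("event replay semantics: empty and single-event streams", {
  p <- wc_params(w0 = 0.2, w_sum = 2, h = 0.01, N = 10)
  empty <- stochwc:::new_event_stream(numeric(0), character(0), integer(0),
                                      init = c(k = 3, l = 2), params = p,
                                      t0 = 0, t_end = 10)
  rs <- rate_series_from_events(empty, dt_sample = 1)
  expect_true(all(rs$k == 3) && all(rs$l == 2))
  one <- stochwc:::new_event_stream(5.3, "E", 1L, init = c(k = 3, l = 2),
                                    params = p, t0 = 0, t_end = 10)
  rs1 <- rate_series_from_events(one, dt_sample = 1)
  expect_equal(rs1$k, c(rep(3, 6), rep(4, 5)))  # steps between samples 5 and 6
  # replay that violates bounds is rejected
  bad <- stochwc:::new_event_stream(c(1, 2), c("E", "E"), c(-1L, -1L),
                                    init = c(k = 1, l = 0), params = p,
                                    t0 = 0, t_end = 3)
  expect_error(rate_series_from_events(bad, 1), "corrupt")
})

test_that("mean reconstructed rate equals spike count over N * duration", {
  p <- wc_params(w0 = 0.2, w_sum = 2, h = 0.05, N = 50)
  sim <- wc_gillespie(p, t_max = 3000, seed = 3, record = "events",
                      burn_in = 200)
  n_spk <- length(spike_times(sim$events))
  # total activation rate over both populations is 2 N R, so the expected
  # pooled spike count is 2 N * mean(R) * duration
  expect_equal(2 * p$N * sim$moments$mean_rate * sim$moments$duration, n_spk,
               tolerance = 3 / sqrt(n_spk) + 0.01)
})

test_that("per-neuron and aggregated engines agree statistically", {
  p <- wc_params(w0 = 0.15, w_sum = 2, h = 0.02, N = 100)
  t_max <- 8000
  sa <- wc_gillespie(p, t_max = t_max, seed = 4, record = "none", burn_in = 300)
  sp <- wc_gillespie(p, t_max = t_max, seed = 5, mode = "per_neuron",
                     record = "none", burn_in = 300)
  tau <- stable_fixed_point(p)$tau1
  se <- sqrt(time_avg_se(sa$moments$var_sigma, tau, t_max)^2 +
               time_avg_se(sp$moments$var_sigma, tau, t_max)^2)
  expect_lt(abs(sa$moments$mean_sigma - sp$moments$mean_sigma), 3 * se)
  expect_lt(abs(sa$moments$var_sigma / sp$moments$var_sigma - 1), 0.25)
})

test_that("excitation/inhibition imbalance vanishes as a 1/N finite-size correction", {
  # the mean-field fixed point has Delta0 = 0; at finite N the positive
  # covariance between f(s) and Delta leaves a small negative O(1/N) bias
  m <- vapply(c(100, 400, 1600), function(N) {
    p <- wc_params(w0 = 0.15, w_sum = 2, h = 0.02, N = N)
    wc_gillespie(p, t_max = 3e4, seed = 6, record = "none",
                 burn_in = 500)$moments$mean_delta
  }, 0)
  expect_true(all(abs(m) < 5 / c(100, 400, 1600)))
  expect_true(all(diff(abs(m)) < 0))
})

test_that("small-N Gillespie matches the master-equation oracle", {
  p <- wc_params(w0 = 0.2, w_sum = 1, h = 0.01, N = 3)
  pim <- master_equation_stationary(p)
  sim <- wc_gillespie(p, t_max = 1.5e6, seed = 7, record = "series",
                      dt_sample = 1, burn_in = 200)
  emp <- table(factor(sim$series$k * 4 + sim$series$l, levels = 0:15)) /
    length(sim$series$k)
  tv <- 0.5 * sum(abs(as.numeric(emp) - as.vector(t(pim))))
  expect_lt(tv, 0.01)
})

test_that("stationary <Sigma> approaches Sigma0 as N grows", {
  S0 <- stable_fixed_point(wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-3,
                                     N = 1))$sigma0
  gaps <- vapply(c(1e3, 1e4, 1e5), function(N) {
    p <- wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-3, N = N)
    sim <- wc_gillespie(p, t_max = 1.2e4, seed = 8, record = "none",
                        burn_in = 3e3)
    abs(sim$moments$mean_sigma - S0)
  }, 0)
  expect_true(all(diff(gaps) < 0))
})

test_that("N Var(R) matches the analytic normalised variance within 10%", {
  p <- wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-3, N = 1e4)
  sRR <- rate_statistics(wc_linear_noise(p))$sigma_RR
  sim <- wc_gillespie(p, t_max = 6e4, seed = 9, record = "none", burn_in = 2e3)
  expect_equal(p$N * sim$moments$var_rate, sRR, tolerance = 0.1)
})

test_that("noise-free Langevin flow converges to the fixed point", {
  p <- wc_params(w0 = 0.3, w_sum = 5, h = 1e-3, N = 1e4)
  S0 <- stable_fixed_point(p)$sigma0
  for (k0 in c(0, 2000, 9000)) {
    sim <- wc_langevin(p, t_max = 600, seed = 10, noise = FALSE,
                       burn_in = 0, init = c(k = k0, l = k0 / 2),
                       record = "none")
    expect_equal(sim$moments$mean_rate > 0, TRUE)
    # final state: read back through a short recorded tail
    sim2 <- wc_langevin(p, t_max = 600, seed = 10, noise = FALSE,
                        burn_in = 500, init = c(k = k0, l = k0 / 2),
                        dt_sample = 10)
    expect_equal(mean(sim2$series$k) / p$N, S0, tolerance = 1e-3)
    expect_equal(mean(sim2$series$l) / p$N, S0, tolerance = 1e-3)
  }
})

test_that("Langevin warns when the step is too coarse", {
  p <- wc_params(w0 = 0.2, w_sum = 2, h = 0.01, N = 100)
  expect_warning(wc_langevin(p, t_max = 50, dt = 15, seed = 1, burn_in = 0,
                             record = "none"), "unstable")
})

test_that("simulations are reproducible given a seed", {
  p <- wc_params(w0 = 0.2, w_sum = 2, h = 0.01, N = 50)
  a <- wc_gillespie(p, t_max = 500, seed = 42, record = "series", burn_in = 0)
  b <- wc_gillespie(p, t_max = 500, seed = 42, record = "series", burn_in = 0)
  expect_identical(a$series$k, b$series$k)
  expect_identical(a$moments, b$moments)
})
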