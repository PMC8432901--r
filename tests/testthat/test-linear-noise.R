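test_that("decoupled populations give the diagonal OU covariance", {
  # w_E = w_I = 0: no feed-forward term, two independent OU modes
  p <- wc_params(w_E = 0, w_I = 0, h = 0.2)
  sol <- wc_linear_noise(p)
  fp <- sol$fixed_point
  expect_equal(sol$w_ff, 0)
  expect_equal(sol$cov[1, 2], 0)
  expect_equal(sol$cov[1, 1], p$alpha * fp$sigma0 * fp$tau1 / 2)
  expect_equal(sol$cov[2, 2], p$alpha * fp$sigma0 * fp$tau2 / 2)
})

test_that("stationary covariance solves the Lyapunov equation to 1e-12", {
  for (w0 in c(0.05, 0.1, 0.2, 1)) {
    sol <- wc_linear_noise(wc_params(w0 = w0, w_sum = 13.8, h = 1e-5))
    res <- sol$M %*% sol$cov + sol$cov %*% t(sol$M) +
      diag(sol$noise_amp, 2)
    expect_lt(max(abs(res)), 1e-12 * max(1, max(abs(sol$cov))))
    # symmetric positive semi-definite
    expect_equal(sol$cov[1, 2], sol$cov[2, 1])
    expect_true(all(eigen(sol$cov, symmetric = TRUE)$values >= -1e-15))
  }
})

test_that("covariance inverse matches its closed form", {
  sol <- wc_linear_noise(wc_params(w0 = 0.3, w_sum = 5, h = 1e-4))
  t1 <- sol$fixed_point$tau1; t2 <- sol$fixed_point$tau2; w <- sol$w_ff
  c0 <- sol$noise_amp
  pref <- 2 / (c0 * (2 * t1 * t2 + t2^2 + t1^2 * (1 + w^2 * t2^2)) /
                 (t1 + t2))
  inv_cf <- pref * matrix(c((t1 + t2) / t1, -w * t2, -w * t2,
                            (t1 + t2 + w^2 * t1 * t2^2) / t2), 2, 2)
  expect_equal(unname(solve(sol$cov)), inv_cf, tolerance = 1e-10)
})

test_that("known spot value: sigma_DD at w0 = 1, h = 1e-5", {
  sol <- wc_linear_noise(wc_params(w0 = 1, w_sum = 13.8, h = 1e-5))
  expect_equal(sol$fixed_point$tau2, 1.2434, tolerance = 1e-4)
  expect_equal(sol$cov[2, 2], 0.05445, tolerance = 1e-3)
})

test_that("unstable or degenerate regimes are refused", {
  # marginal point h = 0, w0 = w0c: tau1 diverges, quiescent root marginal
  expect_error(wc_linear_noise(wc_params(w0 = 0.1, w_sum = 1, h = 0)),
               "stable|stationary")
})

test_that("correlation matrix: C(0) = cov, closed forms, expm oracle", {
  sol <- wc_linear_noise(wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-5))
  expect_equal(correlation_matrix(sol, 0), sol$cov)
  fp <- sol$fixed_point; c0 <- sol$noise_amp
  t1 <- fp$tau1; t2 <- fp$tau2; w <- sol$w_ff
  for (t in c(0.5, 2, 10, 40)) {
    Ct <- correlation_matrix(sol, t)
    # C_DD(t) = (alpha Sigma0 tau2 / 2) exp(-t/tau2)
    expect_equal(Ct[2, 2], c0 * t2 / 2 * exp(-t / t2), tolerance = 1e-12)
    # C_DS(t) = (alpha Sigma0 tau1 tau2 w / (2 (tau1 + tau2))) ... row 2
    expect_equal(Ct[2, 1], c0 * w * t1 * t2^2 / (2 * (t1 + t2)) *
                   exp(-t / t2), tolerance = 1e-12)
    # full matrix against a scaling-and-squaring matrix exponential
    E <- as.matrix(Matrix::expm(sol$M * t))
    expect_equal(unname(Ct), unname(E %*% sol$cov), tolerance = 1e-8)
  }
  expect_error(correlation_matrix(sol, -1), "t")
})

test_that("degenerate equal-time-scale branch matches the expm oracle", {
  # hand-built solution with tau1 = tau2 exercises the t*exp(-t/tau) branch
  sol <- structure(list(fixed_point = list(tau1 = 5, tau2 = 5),
                        w_ff = 0.3, cov = diag(2)), class = "wc_lna")
  M <- matrix(c(-0.2, 0, 0.3, -0.2), 2, 2)
  for (t in c(1, 5, 20)) {
    expect_equal(unname(correlation_matrix(sol, t)),
                 as.matrix(Matrix::expm(M * t)), tolerance = 1e-8)
  }
})

test_that("firing-rate statistics: quadratic form, Fano, degenerate rate", {
  sol <- wc_linear_noise(wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-5))
  st <- rate_statistics(sol)
  qf <- sol$r_sigma^2 * sol$cov[1, 1] +
    2 * sol$r_sigma * sol$r_delta * sol$cov[1, 2] +
    sol$r_delta^2 * sol$cov[2, 2]
  expect_equal(st$sigma_RR, qf)
  expect_equal(st$fano, st$sigma_RR / st$r0)
  expect_equal(st$cv2, st$sigma_RR / st$r0^2)
  # quiescent stable state: R0 = 0 flagged, ratios infinite
  st0 <- rate_statistics(wc_linear_noise(wc_params(w0 = 0.05, w_sum = 1,
                                                   h = 0)))
  expect_true(st0$degenerate_rate)
  expect_identical(st0$fano, Inf)
})

test_that("analytic rate autocorrelation is normalised, decaying, two-mode", {
  # near-critical point: both exponential modes carry positive weight
  sol <- wc_linear_noise(wc_params(w0 = 0.1, w_sum = 13.8, h = 1e-4))
  tmax0 <- max(sol$fixed_point$tau1, sol$fixed_point$tau2)
  tt <- tmax0 * c(0, 0.2, 0.5, 1, 2, 4, 8, 12)
  v <- rate_autocorrelation_analytic(sol, tt)
  expect_equal(v[1], 1)
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1e-4)
  amp <- attr(v, "amplitudes")
  expect_equal(unname(sum(amp)), 1, tolerance = 1e-12)
  # long-time log-slope approaches -1/max(tau1, tau2)
  tmax <- max(sol$fixed_point$tau1, sol$fixed_point$tau2)
  slope <- (log(as.numeric(rate_autocorrelation_analytic(sol, 20 * tmax))) -
              log(as.numeric(rate_autocorrelation_analytic(sol, 15 * tmax)))) /
    (5 * tmax)
  expect_equal(-1 / slope, tmax, tolerance = 1e-3)
})

test_that("relaxation time diverges as 1/|w0 - w0c| at the transition", {
  for (eps in c(1e-2, 1e-3, 1e-4)) {
    # below: quiescent root, tau1 = 1/(beta (w0c - w0)) exactly
    tb <- stable_fixed_point(wc_params(w0 = 0.1 - eps, w_sum = 1, h = 0))$tau1
    expect_equal(tb * eps, 1, tolerance = 1e-12)
    # above: active root, product -> 1 as eps -> 0
    ta <- stable_fixed_point(wc_params(w0 = 0.1 + eps, w_sum = 1, h = 0))$tau1
    expect_equal(ta * eps, 1, tolerance = 30 * eps)
  }
})

test_that("analytic rate autocorrelation matches a Langevin run (large N)", {
  # N large enough that rare downstate excursions are absent and the
  # linear-noise regime holds throughout the record
  p <- wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-6, N = 1e6)
  sol <- wc_linear_noise(p)
  sim <- wc_langevin(p, t_max = 3e4, seed = 61, dt_sample = 0.5)
  ac <- empirical_autocorrelation(sim$series, max_lag = 40)
  t1 <- sol$fixed_point$tau1
  for (lg in c(t1 / 4, t1, 3 * t1)) {
    i <- which.min(abs(ac$lags - lg))
    ana <- rate_autocorrelation_analytic(sol, ac$lags[i])
    expect_lt(abs(ac$values[i] - ana), 3 * ac$se[i] + 0.005)
  }
})
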