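# Ground-truth generators and brute-force oracles. Every estimator in the
# package (power-law MLE, avalanche detectors, autocorrelation, the
# Gillespie engine itself) can be validated against these without any
# Wilson-Cowan-specific assumption.

#' Critical branching-process avalanche fixture
#'
#' Simulates Galton-Watson avalanches with Poisson(`m`) offspring and a
#' single ancestor. Size is the total number of individuals and duration
#' the number of generations. At the critical branching ratio `m = 1`
#' the size and duration tails follow the mean-field branching exponents
#' `tau_S = 3/2` and `tau_T = 2`; subcritical `m < 1` produces an
#' exponential cutoff. (Any finite-variance offspring law gives the same
#' critical exponents; Poisson is used for simplicity.)
#'
#' Avalanches are truncated at `max_generations` (recorded in the
#' metadata); at `m = 1` the truncated fraction is of order
#' `1/max_generations` and does not affect tail fits below the cap.
#'
#' @param m Branching ratio, in (0, 1.2].
#' @param n_avalanches Number of avalanches.
#' @param seed Optional integer seed.
#' @param max_generations Duration cap.
#' @param profiles Keep per-generation counts (for shape analysis).
#' @return An `avalanche_catalog` (durations in generations) with method
#'   `"branching"`.
#' @export
branching_avalanches <- function(m, n_avalanches, seed = NULL,
                                 max_generations = 1e4, profiles = FALSE) {
  if (!is.numeric(m) || m <= 0 || m > 1.2)
    stop("`m` must be in (0, 1.2]", call. = FALSE)
  if (n_avalanches < 1) stop("`n_avalanches` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_avalanches)
  size <- rep(1, n); dur <- rep(1, n)
  z <- rep(1, n)                       # current generation sizes
  alive <- seq_len(n)
  prof <- if (profiles) lapply(seq_len(n), function(i) 1) else NULL
  gen <- 1L
  while (length(alive) && gen < max_generations) {
    z_new <- stats::rpois(length(alive), m * z)
    surv <- z_new > 0
    idx <- alive[surv]
    size[idx] <- size[idx] + z_new[surv]
    dur[idx] <- dur[idx] + 1
    if (profiles)
      for (j in seq_along(idx))
        prof[[idx[j]]] <- c(prof[[idx[j]]], z_new[surv][j])
    z <- z_new[surv]
    alive <- idx
    gen <- gen + 1L
  }
  new_catalog(size, dur, "branching",
              list(m = m, truncated = length(alive),
                   max_generations = max_generations), prof)
}

#' Spike-time realisation of a branching avalanche catalog
#'
#' Turns branching-process avalanches (with stored profiles) into a
#' synthetic spike-time stream: each generation occupies one time bin of
#' width `delta`, spikes are placed uniformly at random inside their bin,
#' and consecutive avalanches are separated by `gap` empty bins -- so
#' [detect_binned()] at bin width `delta` recovers the catalog exactly.
#'
#' @param catalog Branching catalog built with `profiles = TRUE`.
#' @param delta Bin width (ms) given to one generation.
#' @param gap Number of empty bins between avalanches (>= 2).
#' @param seed Optional seed for the within-bin jitter.
#' @return Numeric vector of spike times (ms).
#' @export
branching_spike_times <- function(catalog, delta = 1, gap = 3, seed = NULL) {
  prof <- attr(catalog, "profiles")
  if (is.null(prof)) stop("catalog has no profiles", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- unlist(prof, use.names = FALSE)
  nbins_per_av <- vapply(prof, length, 0L)
  # absolute bin index of each avalanche's first generation
  start_bin <- cumsum(c(0L, utils::head(nbins_per_av + gap, -1L)))
  bin_of_gen <- unlist(mapply(function(s, nb) s + seq_len(nb) - 1L,
                              start_bin, nbins_per_av, SIMPLIFY = FALSE),
                       use.names = FALSE)
  bins <- rep(bin_of_gen, counts)
  sort((bins + stats::runif(length(bins))) * delta)
}

#' Stationary Ornstein-Uhlenbeck series fixture
#'
#' Exact-discretisation OU process `dx = -(x - mean)/tau dt + noise`,
#' sampled at interval `dt`: `x[t+1] = mean + rho (x[t] - mean) +
#' sigma sqrt(1 - rho^2) z` with `rho = exp(-dt/tau)`, started from the
#' stationary law `N(mean, sigma^2)`. Its autocorrelation is exactly
#' `exp(-t/tau)`, making it the null model for correlation-time and
#' threshold-avalanche estimators (threshold excursions of an OU signal
#' have duration exponent 3/2 and, for excess-area sizes, size exponent
#' 4/3).
#'
#' @param tau Correlation time (ms), > 0.
#' @param sigma Stationary standard deviation.
#' @param dt Sampling interval (ms), < `tau`.
#' @param n Number of samples.
#' @param mean Stationary mean.
#' @param seed Optional integer seed.
#' @return A `wc_rate_series` whose `R` field holds the OU signal (the
#'   `k`, `l`, `params` fields are absent; `size_scale` defaults to 1 in
#'   [detect_threshold()]).
#' @export
ou_series <- function(tau, sigma, dt, n, mean = 0, seed = NULL) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (dt >= tau) stop("`dt` must be < `tau`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rho <- exp(-dt / tau)
  innov_sd <- sigma * sqrt(1 - rho^2)
  x <- numeric(n)
  if (sigma == 0) {
    x[] <- mean
  } else {
    z <- stats::rnorm(n)
    # AR(1) recursion: y_1 = sigma z_1, y_t = rho y_{t-1} + innov_sd z_t
    x <- mean + as.numeric(stats::filter(c(sigma * z[1], innov_sd * z[-1]),
                                         rho, method = "recursive"))
  }
  structure(list(t0 = 0, dt_sample = dt, k = NULL, l = NULL, R = x,
                 params = NULL, ou = list(tau = tau, sigma = sigma,
                                          mean = mean)),
            class = "wc_rate_series")
}

#' Power-law distributed samples
#'
#' Inverse-CDF sampling from `P(x) ~ x^(-tau)`, `x >= xmin`. Continuous:
#' `x = xmin * u^(-1/(tau-1))`. Discrete: exact inversion of the
#' zeta-normalised survival function `P(X >= k) = zeta(tau, k) /
#' zeta(tau, xmin)` via a CDF table over the bulk of the support plus
#' integer bisection on the Hurwitz-zeta survival for the far tail.
#'
#' @param tau Exponent, > 1.
#' @param xmin Lower bound (>= 1; integer for discrete samples).
#' @param n Number of samples.
#' @param discrete Logical.
#' @param seed Optional integer seed.
#' @return Numeric vector of samples.
#' @export
powerlaw_samples <- function(tau, xmin = 1, n = 1, discrete = FALSE,
                             seed = NULL) {
  if (tau <= 1) stop("`tau` must be > 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  if (!discrete) return(xmin * u^(-1 / (tau - 1)))
  xmin <- round(xmin)
  K <- as.integer(min(1e6, max(1e4, xmin * 1e3)))
  ks <- xmin:K
  z0 <- hurwitz_zeta(tau, xmin)
  pmf <- ks^(-tau) / z0
  cdf <- cumsum(pmf)
  out <- numeric(n)
  inside <- u <= cdf[length(cdf)]
  out[inside] <- ks[findInterval(u[inside], cdf) + 1L]
  if (any(!inside)) {
    # far tail: find smallest k with survival(k+1) < 1 - u by bisection on
    # the exact zeta survival
    # sampled value is the largest k with survival S(k) >= 1 - u
    S <- function(k) hurwitz_zeta(tau, k) / z0
    out[!inside] <- vapply(u[!inside], function(ui) {
      target <- 1 - ui
      lo <- K + 1; hi <- 2 * lo              # S(lo) >= target holds here
      while (S(hi) >= target) { lo <- hi; hi <- 2 * hi }
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (S(mid) >= target) lo <- mid else hi <- mid
      }
      lo
    }, 0)
  }
  out
}

#' Exact stationary distribution of the small-N master equation
#'
#' Brute-force oracle for the Gillespie engine: builds the full
#' `(N+1)^2 x (N+1)^2` generator of the lumped `(k, l)` chain with
#' transition rates `alpha*k`, `(N-k) f(s)`, `alpha*l`, `(N-l) f(s)` and
#' solves `pi Q = 0` (with the normalisation constraint) by a dense
#' linear solve. Restricted to `N <= 6` (at most 49 states).
#'
#' For `h = 0` the chain is reducible (the all-quiescent state is
#' absorbing) and the stationary law is the point mass at `(0, 0)`,
#' returned with a warning.
#'
#' @param params A [wc_params()] with `N <= 6`.
#' @return `(N+1) x (N+1)` matrix `pi` with `pi[k+1, l+1] = P(k, l)`,
#'   summing to 1, with attributes `mean_sigma` and `mean_delta`.
#' @export
master_equation_stationary <- function(params) {
  p <- as_wc_params(params)
  N <- as.integer(p$N)
  if (N > 6) stop("master-equation oracle restricted to N <= 6", call. = FALSE)
  if (p$h == 0) {
    warning("h = 0: reducible chain; returning point mass at (0, 0)",
            call. = FALSE)
    pi0 <- matrix(0, N + 1, N + 1)
    pi0[1, 1] <- 1
    return(structure(pi0, mean_sigma = 0, mean_delta = 0))
  }
  ns <- (N + 1)^2
  id <- function(k, l) k * (N + 1) + l + 1
  Q <- matrix(0, ns, ns)
  for (k in 0:N) for (l in 0:N) {
    s <- (p$w_E * k - p$w_I * l) / N + p$h
    fs <- activation(s, beta = p$beta)
    i <- id(k, l)
    add <- function(j, rate) {
      Q[i, j] <<- Q[i, j] + rate
      Q[i, i] <<- Q[i, i] - rate
    }
    if (k > 0) add(id(k - 1, l), p$alpha * k)
    if (k < N) add(id(k + 1, l), (N - k) * fs)
    if (l > 0) add(id(k, l - 1), p$alpha * l)
    if (l < N) add(id(k, l + 1), (N - l) * fs)
  }
  A <- t(Q)
  A[ns, ] <- 1                         # replace one balance eq by sum-to-1
  b <- c(numeric(ns - 1), 1)
  pi_vec <- solve(A, b)
  pi_vec[abs(pi_vec) < 1e-15] <- 0
  pim <- matrix(0, N + 1, N + 1, dimnames = list(k = 0:N, l = 0:N))
  for (k in 0:N) for (l in 0:N) pim[k + 1, l + 1] <- pi_vec[id(k, l)]
  kk <- matrix(0:N, N + 1, N + 1)
  ll <- t(kk)
  structure(pim,
            mean_sigma = sum(pim * (kk + ll) / (2 * N)),
            mean_delta = sum(pim * (kk - ll) / (2 * N)))
}
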