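#' Linear-noise approximation around the attractive fixed point
#'
#' Builds the stationary Gaussian description of finite-size fluctuations
#' around the attractive fixed point, obtained from the system-size
#' expansion of the master equation to order `N^(1/2)`. The fluctuations of
#' the mean activity (`xi_Sigma`) and of the excitation/inhibition
#' imbalance (`xi_Delta`) follow the linear stochastic system
#' `d(xi)/dt = M xi + sqrt(alpha*Sigma0) eta(t)` with triangular drift
#' `M = [[-1/tau1, w_ff], [0, -1/tau2]]`, where the feed-forward coupling
#' is `w_ff = (1 - Sigma0) * (w_E + w_I) * f'(s0)`.
#'
#' The stationary covariance is computed both by numerically solving the
#' Lyapunov equation `M sigma + sigma M^T = -alpha*Sigma0*I` and by its
#' closed form; the constructor errors if the two disagree beyond
#' `1e-10` relative (they agree to machine precision in practice).
#'
#' @param params A [wc_params()] object with a stable fixed point.
#' @return An object of class `"wc_lna"`: a list with `params`,
#'   `fixed_point` (see [solve_fixed_points()]), `w_ff` (ms^-1),
#'   `noise_amp` (`alpha*Sigma0`, ms^-1), `M` (2x2 drift, ms^-1), `cov`
#'   (2x2 stationary covariance, rows/cols ordered Sigma, Delta),
#'   `r_sigma` (`dR/dSigma = alpha - 1/tau1`, ms^-1) and `r_delta`
#'   (`dR/dDelta = w_ff`, ms^-1).
#' @examples
#' sol <- wc_linear_noise(wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-5))
#' rate_statistics(sol)$cv2  # approx 2400
#' @export
wc_linear_noise <- function(params) {
  p <- as_wc_params(params)
  fp <- stable_fixed_point(p)
  if (!is.finite(fp$tau1) || fp$tau1 <= 0)
    stop("no stationary linear solution: fixed point unstable or marginal",
         call. = FALSE)
  wff <- (1 - fp$sigma0) * p$w_sum * activation_deriv(fp$s0, beta = p$beta)
  # at the h = 0 quiescent fixed point s0 = 0: use the right-derivative beta
  if (fp$s0 <= 0) wff <- (1 - fp$sigma0) * p$w_sum * p$beta
  M <- matrix(c(-1 / fp$tau1, 0, wff, -1 / fp$tau2), 2, 2,
              dimnames = list(c("Sigma", "Delta"), c("Sigma", "Delta")))
  c0 <- p$alpha * fp$sigma0
  # Lyapunov solve via vectorisation: (I (x) M + M (x) I) vec(sigma) = -vec(D)
  A <- kronecker(diag(2), M) + kronecker(M, diag(2))
  sig_num <- matrix(solve(A, -as.vector(diag(c0, 2))), 2, 2)
  # closed form for the triangular drift
  t1 <- fp$tau1; t2 <- fp$tau2
  szz <- c0 * t2 / 2
  ssz <- c0 / 2 * wff * t1 * t2^2 / (t1 + t2)
  sss <- c0 / 2 * t1 * (1 + wff^2 * t1 * t2^2 / (t1 + t2))
  sig_cf <- matrix(c(sss, ssz, ssz, szz), 2, 2)
  scale <- max(abs(sig_cf), .Machine$double.xmin)
  if (max(abs(sig_num - sig_cf)) > 1e-10 * scale)
    stop("Lyapunov solve and closed-form covariance disagree", call. = FALSE)
  dimnames(sig_cf) <- dimnames(M)
  structure(
    list(params = p, fixed_point = fp, w_ff = wff, noise_amp = c0, M = M,
         cov = sig_cf, r_sigma = p$alpha - 1 / fp$tau1, r_delta = wff),
    class = "wc_lna")
}

#' @export
print.wc_lna <- function(x, ...) {
  fp <- x$fixed_point
  cat("Linear-noise approximation (stochastic Wilson-Cowan)\n")
  cat(sprintf("  Sigma0 = %.6g, R0 = %.4g Hz, tau1 = %.4g ms, tau2 = %.4g ms\n",
              fp$sigma0, fp$r0_Hz, fp$tau1, fp$tau2))
  cat(sprintf("  w_ff = %.4g ms^-1, noise amplitude alpha*Sigma0 = %.4g ms^-1\n",
              x$w_ff, x$noise_amp))
  cat("  stationary covariance (Sigma, Delta):\n")
  print(signif(x$cov, 6))
  invisible(x)
}

#' @export
summary.wc_lna <- function(object, ...) {
  st <- rate_statistics(object)
  out <- c(sigma0 = object$fixed_point$sigma0, R0_Hz = object$fixed_point$r0_Hz,
           tau1 = object$fixed_point$tau1, tau2 = object$fixed_point$tau2,
           w_ff = object$w_ff, sigma_RR = st$sigma_RR, fano = st$fano,
           cv2 = st$cv2)
  class(out) <- "summary.wc_lna"
  out
}

#' @export
print.summary.wc_lna <- function(x, ...) {
  print(unclass(signif(x, 6)))
  invisible(x)
}

# matrix exponential of the triangular drift at lag t (explicit form);
# degenerate equal-time branch when |1/tau1 - 1/tau2| < 1e-12 ms^-1
expM <- function(sol, t) {
  t1 <- sol$fixed_point$tau1; t2 <- sol$fixed_point$tau2; w <- sol$w_ff
  e1 <- exp(-t / t1); e2 <- exp(-t / t2)
  ur <- if (abs(1 / t1 - 1 / t2) < 1e-12) w * t * e1
        else w * t1 * t2 * (e1 - e2) / (t1 - t2)
  matrix(c(e1, 0, ur, e2), 2, 2)
}

#' Analytic time-correlation matrix of the fluctuations
#'
#' Stationary lag-`t` correlation matrix `C(t) = exp(M t) %*% cov` of the
#' fluctuation pair `(xi_Sigma, xi_Delta)`, evaluated with the explicit
#' two-exponential matrix exponential of the triangular drift (with the
#' degenerate `tau1 = tau2` branch handled explicitly). `C(0)` equals the
#' stationary covariance exactly; for negative lags use stationarity,
#' `C_xy(-t) = C_yx(t)`.
#'
#' @param sol A [wc_linear_noise()] solution.
#' @param t Lag in ms, `>= 0` (scalar).
#' @return 2x2 matrix with rows/cols ordered (Sigma, Delta).
#' @export
correlation_matrix <- function(sol, t) {
  stopifnot(inherits(sol, "wc_lna"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("`t` must be a finite scalar >= 0", call. = FALSE)
  out <- expM(sol, t) %*% sol$cov
  dimnames(out) <- dimnames(sol$cov)
  out
}

#' Stationary firing-rate statistics in the linear-noise approximation
#'
#' The firing-rate fluctuation is `xi_R = r_sigma * xi_Sigma + r_delta *
#' xi_Delta`, so its stationary variance (the N-independent normalised
#' variance `sigma_RR = N <(R - R0)^2>`) is the quadratic form
#' `r_sigma^2 sSS + 2 r_sigma r_delta sSD + r_delta^2 sDD` over the
#' covariance entries. Also returned are the Fano factor `sigma_RR / R0`
#' and the squared coefficient of variation `cv2 = sigma_RR / R0^2`; the
#' latter is N times the variance of `R/R0` and sets the system size below
#' which the dynamics is avalanche-like rather than Gaussian.
#'
#' @param sol A [wc_linear_noise()] solution.
#' @return List with `r0` (ms^-1), `r0_Hz`, `sigma_RR` (ms^-2), `fano`
#'   (ms^-1), `cv2` (dimensionless) and `degenerate_rate` (TRUE when
#'   `R0 = 0`, in which case `fano` and `cv2` are `Inf`).
#' @export
rate_statistics <- function(sol) {
  stopifnot(inherits(sol, "wc_lna"))
  s <- sol$cov
  sRR <- sol$r_sigma^2 * s[1, 1] + 2 * sol$r_sigma * sol$r_delta * s[1, 2] +
    sol$r_delta^2 * s[2, 2]
  r0 <- sol$fixed_point$r0
  degenerate <- (r0 == 0)
  list(r0 = r0, r0_Hz = 1000 * r0, sigma_RR = sRR,
       fano = if (degenerate) Inf else sRR / r0,
       cv2 = if (degenerate) Inf else sRR / r0^2,
       degenerate_rate = degenerate)
}

#' Analytic normalised autocorrelation of the firing rate
#'
#' Correlation function of the firing-rate fluctuation,
#' `<xi_R(t) xi_R(0)> = r_sigma^2 CSS(t) + r_sigma r_delta (CSD(t) +
#' CDS(t)) + r_delta^2 CDD(t)`, normalised to 1 at `t = 0`. The result is
#' a combination of two exponentials `A1 exp(-t/tau1) + A2 exp(-t/tau2)`
#' (normalised amplitudes returned as attribute `"amplitudes"`, except in
#' the degenerate `tau1 = tau2` case where a `t exp(-t/tau1)` term
#' appears).
#'
#' @param sol A [wc_linear_noise()] solution.
#' @param t Lag(s) in ms, `>= 0`.
#' @return Numeric vector of normalised correlations, one per lag, with
#'   attribute `"amplitudes"` (named `A1`, `A2`) when non-degenerate.
#' @export
rate_autocorrelation_analytic <- function(sol, t) {
  stopifnot(inherits(sol, "wc_lna"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("`t` must be >= 0 (use stationarity for negative lags)", call. = FALSE)
  rs <- sol$r_sigma; rd <- sol$r_delta
  quad <- function(C) rs^2 * C[1, 1] + rs * rd * (C[1, 2] + C[2, 1]) +
    rd^2 * C[2, 2]
  c0 <- quad(sol$cov)
  if (c0 <= 0) stop("zero rate variance: correlation undefined", call. = FALSE)
  vals <- vapply(t, function(tt) quad(correlation_matrix(sol, tt)), 0) / c0
  t1 <- sol$fixed_point$tau1; t2 <- sol$fixed_point$tau2
  if (abs(1 / t1 - 1 / t2) >= 1e-12) {
    # amplitude matrices: exp(Mt) = E1 exp(-t/tau1) + E2 exp(-t/tau2)
    k <- sol$w_ff * t1 * t2 / (t1 - t2)
    E1 <- matrix(c(1, 0, k, 0), 2, 2)
    E2 <- matrix(c(0, 0, -k, 1), 2, 2)
    attr(vals, "amplitudes") <- c(A1 = quad(E1 %*% sol$cov) / c0,
                                  A2 = quad(E2 %*% sol$cov) / c0)
  }
  vals
}
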