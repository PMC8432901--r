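#' Fixed points of the mean-field dynamics
#'
#' Solves the stationary condition of the deterministic (infinite-N) rate
#' equation, `alpha * Sigma0 = f(w0 * Sigma0 + h) * (1 - Sigma0)`, for the
#' mean activity `Sigma0` on `[0, 1]`, using bracketed root finding on the
#' full `tanh` activation (no small-activity approximation). For `h = 0`
#' the absorbing state `Sigma0 = 0` is always a root; a second, positive
#' root appears for `w0 > w0c = alpha/beta`. For `h > 0` there is exactly
#' one positive root. Each root is annotated with the relaxation times
#' `tau1` (slow, along the mean-activity direction) and `tau2` (fast, along
#' the excitation/inhibition imbalance), the fixed-point firing rate, and a
#' stability flag (`tau1 > 0`). Unstable roots are reported, not dropped.
#'
#' @param params A [wc_params()] object.
#' @param tol Root-finding tolerance on `Sigma0`.
#' @return An object of class `"wc_fixed_points"`: a list of fixed points,
#'   each a list with `sigma0`, `s0`, `r0` (ms^-1), `r0_Hz`, `tau1` (ms),
#'   `tau2` (ms), `stable`. Ordered by `sigma0`.
#' @seealso [stable_fixed_point()], [relaxation_times()], [fixed_point_rate()]
#' @examples
#' solve_fixed_points(wc_params(w0 = 1, w_sum = 1, h = 0))
#' @export
solve_fixed_points <- function(params, tol = 1e-12) {
  p <- as_wc_params(params)
  g <- function(S) activation(p$w0 * S + p$h, beta = p$beta) * (1 - S) -
    p$alpha * S
  roots <- numeric(0)
  if (p$h == 0) {
    roots <- 0
    # positive root exists iff the zero state is unstable (beta*w0 > alpha);
    # immediately above threshold the root is ~ (w0 - w0c)/w0 and may fall
    # below resolvable precision, in which case only the zero root remains
    if (p$beta * p$w0 > p$alpha) {
      lo <- tol
      while (g(lo) <= 0 && lo < 0.5) lo <- lo * 10
      if (g(lo) > 0) {
        r <- stats::uniroot(g, c(lo, 1), tol = tol)$root
        roots <- c(roots, r)
      }
    }
  } else {
    # g(0) = f(h) > 0, g(1) = -alpha < 0: exactly one root in (0, 1)
    r <- stats::uniroot(g, c(0, 1), tol = tol)$root
    roots <- r
  }
  if (length(roots) == 0) stop("no fixed point found in [0, 1]", call. = FALSE)
  out <- lapply(sort(roots), function(S0) {
    tt <- relaxation_times(p, S0)
    r0 <- fixed_point_rate(p, S0)
    list(sigma0 = S0, s0 = p$w0 * S0 + p$h, r0 = r0, r0_Hz = 1000 * r0,
         tau1 = tt[["tau1"]], tau2 = tt[["tau2"]], stable = tt[["tau1"]] > 0)
  })
  structure(out, class = "wc_fixed_points", params = p)
}

#' @export
print.wc_fixed_points <- function(x, ...) {
  cat("Fixed points of the mean-field Wilson-Cowan dynamics\n")
  for (fp in x) {
    cat(sprintf(
      "  Sigma0 = %.6g  R0 = %.4g Hz  tau1 = %.4g ms  tau2 = %.4g ms  [%s]\n",
      fp$sigma0, fp$r0_Hz, fp$tau1, fp$tau2,
      if (fp$stable) "stable" else "unstable"))
  }
  invisible(x)
}

#' Attractive fixed point
#'
#' Convenience accessor returning the unique stable fixed point of
#' [solve_fixed_points()], or erroring if none is stable (possible only for
#' the degenerate marginal case `h = 0`, `w0 = w0c`).
#'
#' @inheritParams solve_fixed_points
#' @return A single fixed-point list (fields as in [solve_fixed_points()]).
#' @export
stable_fixed_point <- function(params, tol = 1e-12) {
  fps <- solve_fixed_points(params, tol = tol)
  st <- Filter(function(fp) fp$stable, fps)
  if (length(st) == 0) stop("no stable fixed point for these parameters",
                            call. = FALSE)
  st[[length(st)]]
}

#' Relaxation times at an activity level
#'
#' Evaluates the exact closed forms for the two relaxation times of the
#' linearised dynamics at mean activity `Sigma0`:
#' `1/tau1 = (1 - Sigma0)^-1 * (alpha - beta*w0*(1 - Sigma0)^2 +
#' alpha^2 * Sigma0^2 * w0 / beta)` and `1/tau2 = alpha / (1 - Sigma0)`.
#' When `Sigma0` solves the fixed-point condition these agree algebraically
#' with the Jacobian forms `1/tau1 = alpha + f(s0) - (1 - Sigma0) w0 f'(s0)`
#' and `1/tau2 = alpha + f(s0)` (via `f' = beta - f^2/beta` and
#' `alpha*Sigma0 = f(s0)(1 - Sigma0)`). A negative `tau1` signals an
#' unstable fixed point and is returned as-is; `tau2` is always positive.
#'
#' @inheritParams solve_fixed_points
#' @param sigma0 Mean activity in `[0, 1)`.
#' @return Named numeric vector `c(tau1 = , tau2 = )` in ms.
#' @export
relaxation_times <- function(params, sigma0) {
  p <- as_wc_params(params)
  if (!is.numeric(sigma0) || length(sigma0) != 1L || !is.finite(sigma0) ||
      sigma0 < 0 || sigma0 >= 1)
    stop("`sigma0` must lie in [0, 1)", call. = FALSE)
  om <- 1 - sigma0
  inv_tau1 <- (p$alpha - p$beta * p$w0 * om^2 +
                 p$alpha^2 * sigma0^2 * p$w0 / p$beta) / om
  inv_tau2 <- p$alpha / om
  c(tau1 = 1 / inv_tau1, tau2 = 1 / inv_tau2)
}

#' Critical coupling w0c
#'
#' The net coupling `w0 = w_E - w_I` at which the quiescent state
#' (`Sigma0 = 0`, `h = 0`) exchanges stability: `w0c = alpha/beta`, the
#' ratio of the deactivation rate to the activation rate scale. With
#' `verify = TRUE` the closed form is cross-checked by locating the sign
#' change of `1/tau1` at `Sigma0 = 0` by bisection in `w0` and asserting
#' agreement to within `tol`.
#'
#' @inheritParams solve_fixed_points
#' @param verify Logical; run the bisection cross-check.
#' @param tol Agreement tolerance for the verification (also the bisection
#'   width).
#' @return `alpha/beta` (with `verify = TRUE`, the bisection estimate is
#'   attached as attribute `"bisection"`).
#' @examples
#' critical_coupling(wc_params(w0 = 0, w_sum = 1))  # 0.1 for the defaults
#' @export
critical_coupling <- function(params, verify = FALSE, tol = 1e-10) {
  p <- as_wc_params(params)
  w0c <- p$alpha / p$beta
  if (verify) {
    inv_tau1_at0 <- function(w0) p$alpha - p$beta * w0  # Sigma0 = 0 limit
    lo <- 0; hi <- max(2 * w0c, 1)
    if (inv_tau1_at0(lo) <= 0 || inv_tau1_at0(hi) >= 0)
      stop("bisection bracket invalid", call. = FALSE)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (inv_tau1_at0(mid) > 0) lo <- mid else hi <- mid
    }
    est <- (lo + hi) / 2
    if (abs(est - w0c) > max(tol, 1e-10) * max(1, w0c))
      stop("bisection estimate disagrees with alpha/beta", call. = FALSE)
    return(structure(w0c, bisection = est))
  }
  w0c
}

#' Firing rate at a given activity level
#'
#' The mean-field instantaneous firing rate per neuron,
#' `R0 = (1 - Sigma0) * f(w0*Sigma0 + h)`, in ms^-1. Evaluated at the
#' attractive fixed point this is the order parameter of the transition:
#' for `h = 0` it vanishes for `w0 <= w0c` and grows linearly in
#' `(w0 - w0c)` just above threshold.
#'
#' @inheritParams relaxation_times
#' @return Firing rate in ms^-1 (multiply by 1000 for Hz).
#' @export
fixed_point_rate <- function(params, sigma0) {
  p <- as_wc_params(params)
  if (!is.numeric(sigma0) || length(sigma0) != 1L || sigma0 < 0 || sigma0 > 1)
    stop("`sigma0` must lie in [0, 1]", call. = FALSE)
  (1 - sigma0) * activation(p$w0 * sigma0 + p$h, beta = p$beta)
}
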