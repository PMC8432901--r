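#' Model parameters for the stochastic Wilson-Cowan network
#'
#' Constructs the parameter set of the two-population (excitatory/inhibitory)
#' stochastic Wilson-Cowan model with all-to-all symmetric coupling. Each of
#' the `N` excitatory and `N` inhibitory neurons is a two-state Markov unit:
#' active neurons deactivate at rate `alpha`; quiescent neurons activate at
#' rate `f(s)`, where `s = (w_E k - w_I l)/N + h` is the common synaptic
#' input (`k`, `l` active counts) and `f` is the saturating activation
#' function with slope scale `beta` (see [activation()]).
#'
#' All rates are in ms^-1; `h` and the weights are dimensionless (membrane
#' potentials are measured in units of 1 mV, so the threshold distance `s`
#' and the synaptic weights carry no explicit unit). Firing rates are
#' converted to Hz (x1000) only at reporting boundaries.
#'
#' The coupling can be given either as the excitatory/inhibitory pair
#' `(w_E, w_I)` or as the net coupling and total coupling pair
#' `(w0 = w_E - w_I, w_sum = w_E + w_I)`; the two parameterisations are
#' exactly interconvertible (`w_E = (w_sum + w0)/2`, `w_I = (w_sum - w0)/2`).
#' `w0` is the control parameter of the critical transition; its critical
#' value is `w0c = alpha/beta` (see [critical_coupling()]).
#'
#' @param alpha Deactivation rate (ms^-1), > 0.
#' @param beta Activation rate scale (ms^-1), > 0.
#' @param w_E,w_I Excitatory and inhibitory synaptic weights (>= 0). Supply
#'   either these or `w0` and `w_sum`.
#' @param w0,w_sum Net (`w_E - w_I`) and total (`w_E + w_I`) coupling;
#'   alternative parameterisation.
#' @param h External input (dimensionless), >= 0.
#' @param N Neurons per population (`N_E = N_I = N`), >= 1.
#' @return An object of class `"wc_params"`: a list with fields `alpha`,
#'   `beta`, `w_E`, `w_I`, `h`, `N` and read-only derived fields `w0`,
#'   `w_sum`.
#' @examples
#' p <- wc_params(w0 = 0.1, w_sum = 13.8, h = 1e-6, N = 1e5)
#' p$w_E - p$w_I  # equals w0 exactly
#' @export
wc_params <- function(alpha = 0.1, beta = 1, w_E = NULL, w_I = NULL,
                      w0 = NULL, w_sum = NULL, h = 0, N = 1L) {
  if (is.null(w_E) != is.null(w_I))
    stop("supply both `w_E` and `w_I`, or neither", call. = FALSE)
  if (!is.null(w_E) && (!is.null(w0) || !is.null(w_sum)))
    stop("supply either (w_E, w_I) or (w0, w_sum), not both", call. = FALSE)
  if (is.null(w_E)) {
    if (is.null(w0) || is.null(w_sum))
      stop("supply both `w0` and `w_sum`", call. = FALSE)
    w_E <- (w_sum + w0) / 2
    w_I <- (w_sum - w0) / 2
  } else {
    w0 <- w_E - w_I
    w_sum <- w_E + w_I
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(h), length(h) == 1L, is.finite(h),
            is.numeric(N), length(N) == 1L, is.finite(N))
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (h < 0) stop("`h` must be >= 0", call. = FALSE)
  if (N < 1 || N != round(N)) stop("`N` must be a positive integer", call. = FALSE)
  if (w_E < 0 || w_I < 0)
    stop("`w_E` and `w_I` must be >= 0 (inhibition enters with its own sign)",
         call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, w_E = w_E, w_I = w_I, h = h,
         N = as.double(N), w0 = w0, w_sum = w_sum),
    class = "wc_params")
}

#' @export
print.wc_params <- function(x, ...) {
  cat("Stochastic Wilson-Cowan parameters\n")
  cat(sprintf("  alpha = %g ms^-1, beta = %g ms^-1\n", x$alpha, x$beta))
  cat(sprintf("  w_E = %g, w_I = %g  (w0 = %g, w_sum = %g; w0c = %g)\n",
              x$w_E, x$w_I, x$w0, x$w_sum, x$alpha / x$beta))
  cat(sprintf("  h = %g, N = %g per population\n", x$h, x$N))
  invisible(x)
}

as_wc_params <- function(x) {
  if (inherits(x, "wc_params")) return(x)
  stop("expected a `wc_params` object; see wc_params()", call. = FALSE)
}

#' Neuronal activation function
#'
#' Rate at which a quiescent neuron becomes active, as a function of its
#' synaptic input `s` (distance of the membrane potential from threshold,
#' dimensionless): `beta * tanh(s)` for `s > 0` and 0 otherwise. The
#' function is continuous at `s = 0` and bounded by `beta`.
#'
#' @param s Synaptic input (any numeric vector; must be finite).
#' @param params A [wc_params()] object (only `beta` is used), or `NULL` to
#'   use `beta` directly.
#' @param beta Activation rate scale (ms^-1), used when `params` is `NULL`.
#' @return Activation rate(s) in ms^-1, same length as `s`.
#' @examples
#' activation(c(-0.5, 0, 0.8755))
#' @export
activation <- function(s, params = NULL, beta = 1) {
  if (!is.null(params)) beta <- as_wc_params(params)$beta
  if (!is.numeric(s) || anyNA(s) || any(!is.finite(s)))
    stop("`s` must be finite numeric", call. = FALSE)
  ifelse(s > 0, beta * tanh(s), 0)
}

# derivative f'(s); zero branch for s <= 0 (used only at interior points)
activation_deriv <- function(s, beta = 1) {
  ifelse(s > 0, beta * (1 - tanh(s)^2), 0)
}
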