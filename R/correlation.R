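# Empirical autocorrelation of the firing rate and extraction of the
# maximum correlation time from the exponential tail -- the observable
# whose divergence signals critical slowing down.

#' Empirical autocorrelation of a rate series
#'
#' Computes the normalised stationary autocorrelation
#' `C(t) = (<R(t'+t) R(t')> - <R>^2) / (<R^2> - <R>^2)` on the uniform
#' sampling grid by fast (FFT-based) convolution, using the plug-in
#' (biased) variance normalisation for stability at long lags. Per-lag
#' standard errors are estimated by non-overlapping batch means: the
#' record is split into `n_batches` segments, the autocorrelation is
#' computed per segment, and the standard error of the batch mean is
#' reported.
#'
#' @param series A `wc_rate_series`.
#' @param max_lag Largest lag (ms).
#' @param burn_in Initial time (ms) of the record to discard (on top of
#'   any burn-in already discarded at simulation time).
#' @param n_batches Number of batches for the standard errors (>= 20
#'   recommended; fewer are allowed but noisier).
#' @return Object of class `"wc_acf"`: list with `lags` (ms), `values`,
#'   `se`, `n_samples`, `dt`.
#' @export
empirical_autocorrelation <- function(series, max_lag, burn_in = 0,
                                      n_batches = 20) {
  R <- series$R
  dt <- series$dt_sample
  drop <- floor(burn_in / dt)
  if (drop > 0) R <- R[-seq_len(drop)]
  nlag <- floor(max_lag / dt)
  if (length(R) < 10 * nlag)
    stop("record too short: need length >= 10 * max_lag after burn-in",
         call. = FALSE)
  if (stats::var(R) == 0)
    stop("constant series: autocorrelation undefined", call. = FALSE)
  vals <- acf_fft(R, nlag)
  # batch-means standard errors
  bl <- floor(length(R) / n_batches)
  bv <- vapply(seq_len(n_batches), function(b) {
    seg <- R[((b - 1) * bl + 1):(b * bl)]
    if (stats::var(seg) == 0) rep(NA_real_, nlag + 1) else acf_fft(seg, nlag)
  }, numeric(nlag + 1))
  se <- apply(bv, 1, stats::sd, na.rm = TRUE) /
    sqrt(rowSums(!is.na(bv)))
  structure(list(lags = dt * (0:nlag), values = vals, se = se,
                 n_samples = length(R), dt = dt),
            class = "wc_acf")
}

# biased-normalisation autocorrelation by FFT, lags 0..nlag
acf_fft <- function(x, nlag) {
  n <- length(x)
  x <- x - mean(x)
  m <- stats::nextn(n + nlag, 2)
  f <- stats::fft(c(x, numeric(m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(nlag + 1)] / m
  ac / ac[1]
}

#' @export
print.wc_acf <- function(x, ...) {
  cat(sprintf(
    "Empirical autocorrelation: %d lags up to %g ms (%d samples, dt = %g ms)\n",
    length(x$lags) - 1, max(x$lags), x$n_samples, x$dt))
  invisible(x)
}

#' @export
plot.wc_acf <- function(x, log = "y", ...) {
  keep <- x$values > 0
  graphics::plot(x$lags[keep], x$values[keep], log = log, type = "l",
                 xlab = "lag (ms)", ylab = "C(t)", ...)
  invisible(x)
}

#' Integrated correlation time
#'
#' The integrated autocorrelation time `tau_int = dt * (1/2 + sum_t C(t))`,
#' summed over the lags whose correlation exceeds `se_factor` times its
#' standard error (a significance cut that stops the sum at the noise
#' floor). For a single exponential `tau_int ~ tau`; more generally it is
#' an amplitude-weighted mean of the mode time scales. It is the robust
#' summary of correlation range for records too short to pin down the far
#' exponential tail, for which [fit_correlation_time()] needs
#' high-precision long-lag estimates.
#'
#' @param corr A `wc_acf`.
#' @param se_factor Significance multiple for including a lag.
#' @return Integrated correlation time (ms).
#' @export
integrated_correlation_time <- function(corr, se_factor = 3) {
  stopifnot(inherits(corr, "wc_acf"))
  keep <- corr$lags > 0 & is.finite(corr$values) &
    corr$values > se_factor * corr$se
  corr$dt * (0.5 + sum(corr$values[keep]))
}

#' Maximum correlation time from the exponential tail
#'
#' Fits a single exponential to the long-time tail of a (normalised)
#' correlation function by least squares on `log C` versus lag,
#' restricted to the lags where the correlation lies inside `window`
#' (fractions of the peak value; non-positive values are excluded). The
#' returned time is `-1/slope`. For a correlation that is a mixture of
#' exponentials this extracts the slowest mode as the window moves to
#' small values.
#'
#' @param corr A `wc_acf`, or a list with `lags` and `values`.
#' @param window `c(lo, hi)` correlation window; default `c(0.01, 0.2)`.
#' @return List with `tau_max` (ms), `n_lags`, `window`, `fit`.
#' @export
fit_correlation_time <- function(corr, window = c(0.01, 0.2)) {
  lags <- corr$lags; v <- corr$values
  keep <- is.finite(v) & v > 0 & v >= window[1] & v <= window[2] & lags > 0
  if (sum(keep) < 5)
    stop("fewer than 5 positive correlation values inside the window",
         call. = FALSE)
  fit <- stats::lm(log(v[keep]) ~ lags[keep])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= -1e-15)
    stop("non-decaying tail: cannot extract a correlation time", call. = FALSE)
  list(tau_max = -1 / slope, n_lags = sum(keep), window = window, fit = fit)
}
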