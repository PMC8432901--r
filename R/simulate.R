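# Simulation layer: exact Gillespie simulation of the Markov jump process
# and Euler-Maruyama integration of the equivalent nonlinear Langevin
# equations. Both engines share the stationary-statistics contract: a
# burn-in period is discarded before any time-averaged quantity.

default_burn_in <- function(params) {
  fp <- tryCatch(stable_fixed_point(params), error = function(e) NULL)
  if (is.null(fp)) return(0)
  20 * max(fp$tau1, fp$tau2)
}

default_init <- function(params) {
  fp <- tryCatch(stable_fixed_point(params), error = function(e) NULL)
  s0 <- if (is.null(fp)) 0 else fp$sigma0
  k0 <- round(params$N * s0)
  c(k = k0, l = k0)
}

new_rate_series <- function(t0, dt, k, l, params) {
  p <- as_wc_params(params)
  s <- (p$w_E * k - p$w_I * l) / p$N + p$h
  R <- (1 - (k + l) / (2 * p$N)) * activation(s, beta = p$beta)
  structure(list(t0 = t0, dt_sample = dt, k = k, l = l, R = R, params = p),
            class = "wc_rate_series")
}

#' Sampling times of a rate time series
#' @param x A `wc_rate_series` object.
#' @return Numeric vector of sample times (ms).
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "wc_rate_series"))
  x$t0 + x$dt_sample * (seq_along(x$R) - 1)
}

#' @export
print.wc_rate_series <- function(x, ...) {
  cat(sprintf(
    "Rate time series: %d samples, dt = %g ms, t0 = %g ms\n",
    length(x$R), x$dt_sample, x$t0))
  cat(sprintf("  mean R = %.4g Hz, max R = %.4g Hz\n",
              1000 * mean(x$R), 1000 * max(x$R)))
  invisible(x)
}

#' @export
plot.wc_rate_series <- function(x, max_points = 20000L, ...) {
  tt <- series_time(x); R <- 1000 * x$R
  if (length(tt) > max_points) {
    idx <- unique(round(seq(1, length(tt), length.out = max_points)))
    tt <- tt[idx]; R <- R[idx]
  }
  graphics::plot(tt, R, type = "l", xlab = "time (ms)",
                 ylab = "firing rate (Hz)", ...)
  invisible(x)
}

new_event_stream <- function(t, pop, delta, init, params, seed = NA,
                             t0 = 0, t_end = NULL) {
  ev <- data.frame(t = as.double(t),
                   pop = factor(pop, levels = c("E", "I")),
                   delta = as.integer(delta))
  if (is.null(t_end)) t_end <- if (nrow(ev)) max(ev$t) else t0
  structure(list(events = ev, initial_state = init, params = params,
                 seed = seed, t0 = t0, t_end = t_end),
            class = "wc_event_stream")
}

#' @export
print.wc_event_stream <- function(x, ...) {
  cat(sprintf("Spike event stream: %d events, initial state k = %d, l = %d\n",
              nrow(x$events), x$initial_state[["k"]], x$initial_state[["l"]]))
  invisible(x)
}

#' Spike (activation) times of an event stream
#' @param stream A `wc_event_stream`.
#' @return Times (ms) of quiescent-to-active transitions of either
#'   population; deactivations are never counted as spikes.
#' @export
spike_times <- function(stream) {
  stopifnot(inherits(stream, "wc_event_stream"))
  stream$events$t[stream$events$delta > 0]
}

#' Exact stochastic simulation of the Wilson-Cowan Markov process
#'
#' Simulates the continuous-time Markov chain of `2N` two-state neurons with
#' the Gillespie algorithm. The default `"aggregated"` engine exploits the
#' exchangeability of the identical all-to-all units and simulates the
#' lumped chain on the active counts `(k, l)` with four transition channels
#' of rates `alpha*k`, `(N-k) f(s)`, `alpha*l`, `(N-l) f(s)` -- an exact
#' O(1)-per-event reformulation. The `"per_neuron"` engine follows the
#' textbook per-unit algorithm literally (per-neuron rates, categorical
#' selection with probability `r_i/r`) and is retained for fidelity checks;
#' the two produce statistically indistinguishable trajectories.
#'
#' With `h = 0` the all-quiescent state `(0, 0)` is absorbing: once
#' reached, the simulation legitimately idles until `t_max` (flagged via
#' `$absorbed`, not an error).
#'
#' Time-averaged stationary moments of the activity `Sigma = (k+l)/2N`, the
#' imbalance `Delta = (k-l)/2N` and the firing rate `R` are accumulated
#' exactly (time-weighted over the piecewise-constant trajectory) after
#' discarding `burn_in`; the trajectory can additionally be recorded as a
#' uniformly sampled series, as per-bin spike counts (for time-binned
#' avalanche detection without storing events), and/or as a full event
#' stream.
#'
#' @param params A [wc_params()] object.
#' @param t_max Total simulated time (ms).
#' @param seed Optional integer seed (applied via [set.seed()]; recorded in
#'   the result).
#' @param mode `"aggregated"` (default) or `"per_neuron"`.
#' @param record Any subset of `c("series", "events", "bins")`; empty for
#'   moments only.
#' @param dt_sample Sampling interval (ms) for the recorded series.
#' @param delta_bin Bin width (ms) for recorded spike-bin counts.
#' @param theta Threshold (ms^-1) for online exact avalanche recording
#'   (used when `"avalanches"` is in `record`): excursions of the
#'   piecewise-constant rate `R(t)` strictly above `theta` are delimited
#'   at event resolution, with exact duration, rate integral, excess-rate
#'   integral and spike count per excursion (see
#'   [exact_threshold_catalog()]).
#' @param burn_in Time (ms) discarded before all stationary statistics and
#'   recordings; default `20 * max(tau1, tau2)` of the attractive fixed
#'   point.
#' @param init Initial `c(k, l)`; default `round(N * Sigma0)` for both.
#' @param max_events Cap on stored events (recording stops, with a flag,
#'   beyond it).
#' @return Object of class `"wc_sim"`: list with `params`, `engine`,
#'   `mode`, `seed`, `t_max`, `burn_in`, `moments` (time-averaged
#'   `mean_sigma`, `var_sigma`, `mean_delta`, `var_delta`, `mean_rate`
#'   (ms^-1), `mean_rate_Hz`, `var_rate`, `spike_count`, `duration`),
#'   `n_events`, `absorbed`, and the requested `series`
#'   (`wc_rate_series`), `events` (`wc_event_stream`), `bins` (list with
#'   `counts`, `delta`).
#' @examples
#' p <- wc_params(w0 = 0.2, w_sum = 13.8, h = 1e-3, N = 200)
#' sim <- wc_gillespie(p, t_max = 2000, seed = 1, burn_in = 200)
#' sim$moments$mean_rate_Hz
#' @export
wc_gillespie <- function(params, t_max, seed = NULL,
                         mode = c("aggregated", "per_neuron"),
                         record = "series", dt_sample = 1, delta_bin = 1,
                         theta = 0, burn_in = NULL, init = NULL,
                         max_events = 5e7) {
  p <- as_wc_params(params)
  mode <- match.arg(mode)
  if (!is.numeric(t_max) || t_max <= 0) stop("`t_max` must be > 0", call. = FALSE)
  record <- if (length(record) == 1 && identical(record, "none")) character(0)
            else match.arg(record, c("series", "events", "bins", "avalanches"),
                           several.ok = TRUE)
  if (is.null(burn_in)) burn_in <- default_burn_in(p)
  if (burn_in >= t_max)
    stop("`burn_in` must be smaller than `t_max` (default is 20*max(tau1, tau2))",
         call. = FALSE)
  if (is.null(init)) init <- default_init(p)
  if (any(init < 0) || any(init > p$N)) stop("invalid initial state", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (mode == "aggregated") {
    raw <- gillespie_agg_cpp(p$alpha, p$beta, p$w_E, p$w_I, p$h, p$N,
                             t_max, burn_in, init[["k"]], init[["l"]],
                             dt_sample, "series" %in% record, delta_bin,
                             "bins" %in% record, "events" %in% record,
                             max_events, "avalanches" %in% record, theta)
  } else {
    raw <- gillespie_per_neuron_cpp(p$alpha, p$beta, p$w_E, p$w_I, p$h,
                                    as.integer(p$N), t_max, burn_in,
                                    as.integer(init[["k"]]),
                                    as.integer(init[["l"]]),
                                    "events" %in% record, max_events)
    if ("series" %in% record || "bins" %in% record)
      stop("per_neuron mode records events only", call. = FALSE)
  }
  out <- build_sim(raw, p, engine = "gillespie", mode = mode, seed = seed,
                   t_max = t_max, burn_in = burn_in, record = record,
                   dt_sample = dt_sample, delta_bin = delta_bin, init = init)
  out
}

build_sim <- function(raw, p, engine, mode, seed, t_max, burn_in, record,
                      dt_sample, delta_bin, init) {
  Tn <- raw$T_stat
  mom <- list(
    mean_sigma = raw$int_S / Tn, var_sigma = raw$int_S2 / Tn - (raw$int_S / Tn)^2,
    mean_delta = raw$int_D / Tn, var_delta = raw$int_D2 / Tn - (raw$int_D / Tn)^2,
    mean_rate = raw$int_R / Tn, mean_rate_Hz = 1000 * raw$int_R / Tn,
    var_rate = raw$int_R2 / Tn - (raw$int_R / Tn)^2,
    spike_count = raw$spikes, duration = Tn)
  out <- list(params = p, engine = engine, mode = mode,
              seed = if (is.null(seed)) NA else seed, t_max = t_max,
              burn_in = burn_in, moments = mom,
              n_events = if (is.null(raw$n_events)) NA else raw$n_events,
              absorbed = isTRUE(raw$absorbed))
  if ("series" %in% record)
    out$series <- new_rate_series(burn_in, dt_sample, raw$k, raw$l, p)
  if ("bins" %in% record)
    out$bins <- list(counts = raw$bin_counts, delta = delta_bin, t0 = burn_in)
  if (!is.null(raw$av_duration))
    out$avalanches <- list(duration = raw$av_duration, int_R = raw$av_int_R,
                           int_excess = raw$av_int_excess,
                           spikes = raw$av_spikes, theta = raw$av_theta)
  if ("events" %in% record) {
    if (isTRUE(raw$event_overflow))
      warning("event recording stopped at `max_events`; stream truncated",
              call. = FALSE)
    # initial state of the *recorded* stream = state at end of burn-in,
    # reconstructed from the final state by reverse replay (valid only when
    # the full post-burn-in stream was kept)
    init_rec <- c(k = NA_integer_, l = NA_integer_)
    if (!isTRUE(raw$event_overflow)) {
      dk <- sum(raw$ev_delta[raw$ev_pop == 0L])
      dl <- sum(raw$ev_delta[raw$ev_pop == 1L])
      init_rec <- c(k = as.integer(raw$k_final - dk),
                    l = as.integer(raw$l_final - dl))
    }
    out$events <- new_event_stream(
      raw$ev_t, c("E", "I")[raw$ev_pop + 1L], raw$ev_delta,
      init = init_rec, params = p,
      seed = if (is.null(seed)) NA else seed, t0 = burn_in, t_end = t_max)
  }
  class(out) <- "wc_sim"
  out
}

#' @export
print.wc_sim <- function(x, ...) {
  cat(sprintf("Stochastic Wilson-Cowan simulation (%s, %s)\n", x$engine,
              x$mode))
  cat(sprintf("  t_max = %g ms (burn-in %g ms discarded), N = %g, seed = %s\n",
              x$t_max, x$burn_in, x$params$N, format(x$seed)))
  m <- x$moments
  cat(sprintf("  mean rate = %.4g Hz, mean Sigma = %.4g, spikes = %g\n",
              m$mean_rate_Hz, m$mean_sigma, m$spike_count))
  if (x$absorbed) cat("  note: absorbing quiescent state reached\n")
  invisible(x)
}

#' Langevin integration of the Wilson-Cowan population dynamics
#'
#' Euler-Maruyama integration of the nonlinear chemical Langevin equations
#' for the continuous active counts `(k, l)`: drift
#' `-alpha*k + f(s)(N - k)` and demographic noise of amplitude
#' `sqrt(alpha*k + f(s)(N - k))` (the argument is clamped at 0 before the
#' square root; `k` and `l` are clamped to `[0, N]` after each step). This
#' is the efficient large-N surrogate for the exact jump process; the two
#' agree statistically for large `N`.
#'
#' @inheritParams wc_gillespie
#' @param dt Integration step (ms); default 1e-3. A warning is issued when
#'   `dt >= 1/alpha` (unstable regime for the deactivation term).
#' @param noise Logical; disable to integrate the deterministic mean-field
#'   flow (testing hook).
#' @param record `"series"` or `"none"`.
#' @return A `"wc_sim"` object (see [wc_gillespie()]); `n_events` is `NA`.
#' @export
wc_langevin <- function(params, t_max, dt = 1e-3, seed = NULL,
                        record = "series", dt_sample = 1, burn_in = NULL,
                        init = NULL, noise = TRUE) {
  p <- as_wc_params(params)
  if (!is.numeric(t_max) || t_max <= 0) stop("`t_max` must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (dt >= 1 / p$alpha)
    warning("`dt` >= 1/alpha: Euler-Maruyama step likely unstable", call. = FALSE)
  record <- if (identical(record, "none")) character(0)
            else match.arg(record, "series", several.ok = TRUE)
  if (is.null(burn_in)) burn_in <- default_burn_in(p)
  if (burn_in >= t_max) stop("`burn_in` must be smaller than `t_max`", call. = FALSE)
  if (is.null(init)) init <- default_init(p)
  if (!is.null(seed)) set.seed(seed)
  raw <- langevin_cpp(p$alpha, p$beta, p$w_E, p$w_I, p$h, p$N, t_max, dt,
                      burn_in, init[["k"]], init[["l"]], dt_sample,
                      "series" %in% record, noise)
  raw$spikes <- NA_real_
  out <- build_sim(raw, p, engine = "langevin", mode = "aggregated",
                   seed = seed, t_max = t_max, burn_in = burn_in,
                   record = record, dt_sample = dt_sample, delta_bin = NA,
                   init = init)
  out
}

#' Reconstruct a uniformly sampled rate series from an event stream
#'
#' Replays the `(k, l)` trajectory from the stream's initial state and
#' samples it on a uniform grid: the value at a grid point is the state
#' immediately after the last event at or before that time. The firing
#' rate is recomputed from the replayed counts via
#' `R = (1 - (k+l)/(2N)) * f((w_E k - w_I l)/N + h)`.
#'
#' @param stream A `wc_event_stream`.
#' @param dt_sample Sampling interval (ms).
#' @return A `wc_rate_series`.
#' @export
rate_series_from_events <- function(stream, dt_sample) {
  stopifnot(inherits(stream, "wc_event_stream"))
  p <- as_wc_params(stream$params)
  ev <- stream$events
  if (nrow(ev) > 1 && any(diff(ev$t) < 0))
    stop("corrupt stream: event times not increasing", call. = FALSE)
  k0 <- stream$initial_state[["k"]]; l0 <- stream$initial_state[["l"]]
  kk <- k0 + cumsum(ifelse(ev$pop == "E", ev$delta, 0L))
  ll <- l0 + cumsum(ifelse(ev$pop == "I", ev$delta, 0L))
  if (length(kk) && (min(kk) < 0 || max(kk) > p$N || min(ll) < 0 ||
                     max(ll) > p$N))
    stop("corrupt stream: replay violates 0 <= k, l <= N", call. = FALSE)
  t0 <- stream$t0
  t_end <- stream$t_end
  grid <- seq(t0, t_end, by = dt_sample)
  idx <- findInterval(grid, ev$t)          # events at grid time included
  k <- c(k0, kk)[idx + 1L]
  l <- c(l0, ll)[idx + 1L]
  new_rate_series(t0, dt_sample, k, l, p)
}
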