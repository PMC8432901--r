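# Avalanche detection and scaling analysis. An avalanche is a burst of
# spiking delimited either by empty time bins (binned definition) or by an
# excursion of the firing rate above a threshold (threshold definition);
# it is characterised by its size S and duration T.

new_catalog <- function(size, duration, method, meta = list(),
                        profiles = NULL) {
  df <- data.frame(size = as.double(size), duration = as.double(duration))
  structure(df, class = c("avalanche_catalog", "data.frame"),
            method = method, meta = meta, profiles = profiles)
}

#' @export
print.avalanche_catalog <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Avalanche catalog: %d avalanches (method: %s)\n", nrow(x),
              attr(x, "method")))
  if (length(meta))
    cat("  ", paste(names(meta), unlist(meta), sep = " = ", collapse = ", "),
        "\n", sep = "")
  if (nrow(x))
    cat(sprintf("  size: median %g, max %g; duration: median %g, max %g\n",
                stats::median(x$size), max(x$size),
                stats::median(x$duration), max(x$duration)))
  invisible(x)
}

#' Time-binned avalanche detection
#'
#' Divides time into bins of width `delta` and defines an avalanche as a
#' maximal run of consecutive bins that each contain at least one spike
#' (a spike being a quiescent-to-active transition of either population;
#' deactivations never count), terminated by one or more empty bins. The
#' size is the total number of spikes in the run and the duration is the
#' number of bins times `delta`. Per-bin spike counts can be retained for
#' shape analysis.
#'
#' The input can be a `wc_event_stream`, a numeric vector of spike times,
#' or a `wc_sim` with recorded spike-bin counts (in which case the bin
#' width is fixed at recording time and `delta` must be a multiple of it).
#'
#' @param x Event stream, spike-time vector, or `wc_sim` with `$bins`.
#' @param delta Bin width (ms).
#' @param profiles Keep per-bin spike counts of each avalanche (needed by
#'   [avalanche_shape()]).
#' @return An `avalanche_catalog` (data frame with columns `size`,
#'   `duration`; method metadata in attributes).
#' @examples
#' detect_binned(c(0.1, 0.2, 0.9, 2.5), delta = 1)  # sizes 3 and 1
#' @export
detect_binned <- function(x, delta = 1, profiles = FALSE) {
  if (!is.numeric(delta) || delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  if (inherits(x, "wc_sim")) {
    if (is.null(x$bins)) stop("simulation has no recorded bin counts", call. = FALSE)
    base_delta <- x$bins$delta
    counts <- x$bins$counts
    if (abs(delta / base_delta - round(delta / base_delta)) > 1e-9)
      stop("`delta` must be a multiple of the recorded bin width", call. = FALSE)
    m <- as.integer(round(delta / base_delta))
    if (m > 1L) {  # coarse-grain by summing groups of m bins
      n <- length(counts); pad <- ceiling(n / m) * m - n
      counts <- colSums(matrix(c(counts, numeric(pad)), nrow = m))
    }
    return(catalog_from_counts(counts, delta, profiles))
  }
  tt <- if (inherits(x, "wc_event_stream")) spike_times(x) else as.numeric(x)
  if (length(tt) == 0)
    return(new_catalog(numeric(0), numeric(0), "binned",
                       list(delta = delta)))
  b <- floor(tt / delta)     # absolute bin grid anchored at t = 0
  cnt <- table(b)
  occ <- as.numeric(names(cnt))            # occupied bins, sorted
  grp <- cumsum(c(1, diff(occ) > 1))       # consecutive-run id
  size <- as.numeric(tapply(as.numeric(cnt), grp, sum))
  nbins <- as.numeric(tapply(occ, grp, length))
  prof <- NULL
  if (profiles) prof <- split(as.numeric(cnt), grp)
  new_catalog(size, nbins * delta, "binned", list(delta = delta), prof)
}

catalog_from_counts <- function(counts, delta, profiles = FALSE) {
  occ <- which(counts > 0)
  if (!length(occ))
    return(new_catalog(numeric(0), numeric(0), "binned", list(delta = delta)))
  grp <- cumsum(c(1, diff(occ) > 1))
  size <- as.numeric(tapply(counts[occ], grp, sum))
  nbins <- as.numeric(tapply(occ, grp, length))
  prof <- if (profiles) split(as.numeric(counts[occ]), grp) else NULL
  new_catalog(size, nbins * delta, "binned", list(delta = delta), prof)
}

#' Threshold-based avalanche detection on a rate series
#'
#' Defines an avalanche as a maximal contiguous interval of samples with
#' firing rate strictly above the threshold `theta`. The duration is the
#' width of the interval; the size follows one of three definitions:
#' 1 = number of spikes in the interval (requires the event stream),
#' 2 = integral of the rate over the interval, 3 = integral of the excess
#' rate `R - theta`. Definitions 2 and 3 coincide for `theta = 0`.
#' Integrals use the trapezoidal rule on the sampling grid; crossings are
#' located at sample resolution (no sub-sample interpolation).
#'
#' Integrated sizes are multiplied by `size_scale`. For a Wilson-Cowan
#' series (per-neuron rate in ms^-1) the default is 1000, i.e. sizes are
#' the integrated rate in Hz x ms -- the working units in which rate
#' signals are reported here, and the convention under which the standard
#' lower fitting bound `S_min = 10` is quoted for size distributions.
#' Multiply instead by `N` (pass `size_scale = series$params$N`) for
#' expected-spike units directly comparable to binned spike counts. For a
#' series without model parameters (e.g. an Ornstein-Uhlenbeck fixture)
#' the default is 1 (raw integral).
#'
#' @param series A `wc_rate_series` (or any object with `$R`, `$dt_sample`).
#' @param theta Threshold (ms^-1), `>= 0`. A threshold at or above
#'   `max(R)` yields an empty catalog (not an error).
#' @param size_def 1, 2 or 3 (see above); default 2.
#' @param events Optional `wc_event_stream`, required for `size_def = 1`.
#' @param size_scale Multiplier for integrated sizes; default 1000 (Hz x
#'   ms units) for a model series, 1 otherwise.
#' @return An `avalanche_catalog` with metadata `theta`, `size_def`.
#' @export
detect_threshold <- function(series, theta, size_def = 2, events = NULL,
                             size_scale = NULL) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("`theta` must be a scalar >= 0", call. = FALSE)
  if (!size_def %in% 1:3) stop("`size_def` must be 1, 2 or 3", call. = FALSE)
  if (size_def == 1 && is.null(events))
    stop("size definition 1 needs the event stream", call. = FALSE)
  R <- series$R; dt <- series$dt_sample
  if (is.null(size_scale))
    size_scale <- if (!is.null(series$params)) 1000 else 1
  up <- R > theta
  if (!any(up))
    return(new_catalog(numeric(0), numeric(0), "threshold",
                       list(theta = theta, size_def = size_def)))
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  dur <- (ends - starts + 1L) * dt
  size <- numeric(length(starts))
  if (size_def == 1) {
    st <- spike_times(events)
    tt <- series_time(series)
    size <- vapply(seq_along(starts), function(i) {
      sum(st >= tt[starts[i]] & st <= tt[ends[i]])
    }, 0)
  } else {
    base <- if (size_def == 3) theta else 0
    csum <- cumsum(R)
    tot <- csum[ends] - csum[starts] + R[starts]        # sum of R over run
    nrun <- ends - starts + 1L
    # trapezoid over the run's samples of (R - base); single-sample runs
    # fall back to the rectangle rule so sizes stay positive
    integ <- dt * (tot - (R[starts] + R[ends]) / 2 - base * (nrun - 1L))
    integ[nrun == 1L] <- dt * (R[starts] - base)[nrun == 1L]
    size <- size_scale * pmax(integ, 0)
  }
  new_catalog(size, dur, "threshold",
              list(theta = theta, size_def = size_def))
}

#' Catalog of exactly detected threshold avalanches
#'
#' Converts the exact (event-resolution) threshold excursions recorded by
#' [wc_gillespie()] with `record = "avalanches"` into an
#' `avalanche_catalog`. Unlike [detect_threshold()], which works at the
#' resolution of the sampled series, these excursions are delimited
#' exactly on the piecewise-constant rate trajectory. Sizes follow the
#' same three definitions: 1 = spike count; 2 = integral of the rate;
#' 3 = integral of the excess rate `R - theta`. Integrated sizes (2, 3)
#' are scaled by `size_scale`, by default 1000 (integrated rate in
#' Hz x ms; see [detect_threshold()]); pass `sim$params$N` for
#' expected-spike units.
#'
#' @param sim A `wc_sim` with recorded avalanches.
#' @param size_def 1, 2 or 3.
#' @param size_scale Multiplier for integrated sizes (default 1000).
#' @return An `avalanche_catalog` with method `"threshold_exact"`.
#' @export
exact_threshold_catalog <- function(sim, size_def = 2, size_scale = 1000) {
  stopifnot(inherits(sim, "wc_sim"))
  av <- sim$avalanches
  if (is.null(av))
    stop("simulation was run without `record = \"avalanches\"`", call. = FALSE)
  if (!size_def %in% 1:3) stop("`size_def` must be 1, 2 or 3", call. = FALSE)
  size <- switch(size_def, av$spikes, size_scale * av$int_R,
                 size_scale * av$int_excess)
  keep <- size > 0 & av$duration > 0
  new_catalog(size[keep], av$duration[keep], "threshold_exact",
              list(theta = av$theta, size_def = size_def))
}

#' Power-law maximum-likelihood fit
#'
#' Fits `P(x) ~ x^(-tau)` for `x >= xmin` by maximum likelihood, following
#' the standard estimator for heavy-tailed data: the continuous closed
#' form `tau = 1 + n / sum(log(x/xmin))` for real-valued data, or the
#' discrete zeta-normalised likelihood (maximised numerically, with the
#' Hurwitz zeta evaluated by Euler-Maclaurin summation) for integer data.
#' The asymptotic standard error is `(tau - 1)/sqrt(n)`; the
#' Kolmogorov-Smirnov distance between fitted and empirical tail CDF is
#' reported as a goodness-of-fit summary. An optional sweep refits over a
#' grid of lower bounds (the protocol used to show exponent convergence in
#' the large-avalanche regime).
#'
#' @param x Positive sample values (sizes or durations).
#' @param xmin Lower bound of the fitting window; only `x >= xmin` enter.
#' @param discrete Logical; use the discrete (integer) likelihood.
#' @param xmin_sweep Optional vector of lower bounds; when given, a data
#'   frame of per-bound fits is attached as attribute `"sweep"`.
#' @return Object of class `"wc_plfit"`: list with `exponent`, `xmin`,
#'   `n_tail`, `stderr`, `ks`, `discrete`, `low_sample` (TRUE when fewer
#'   than 50 tail samples).
#' @examples
#' set.seed(1)
#' x <- powerlaw_samples(tau = 2, xmin = 1, n = 5000)
#' fit_power_law(x, xmin = 1)
#' @export
fit_power_law <- function(x, xmin, discrete = FALSE, xmin_sweep = NULL) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite values to fit", call. = FALSE)
  fit1 <- function(xmin) {
    tail <- x[x >= xmin]
    n <- length(tail)
    if (n < 2) stop("fewer than 2 tail samples", call. = FALSE)
    if (max(tail) == min(tail))
      stop("degenerate sample: all tail values equal", call. = FALSE)
    if (discrete) {
      xi <- round(tail)
      sl <- sum(log(xi))
      opt <- stats::optimize(function(tau) n * log(hurwitz_zeta(tau, xmin)) +
                               tau * sl, c(1 + 1e-8, 25))
      tau <- opt$minimum
      # model tail survival on observed support
      ux <- sort(unique(xi))
      surv_mod <- hurwitz_zeta(tau, ux) / hurwitz_zeta(tau, xmin)
      surv_emp <- 1 - (cumsum(tabulate(factor(xi, levels = ux))) -
                         tabulate(factor(xi, levels = ux))) / n
      ks <- max(abs(surv_mod - surv_emp))
    } else {
      tau <- 1 + n / sum(log(tail / xmin))
      xs <- sort(tail)
      surv_emp <- (n:1) / n
      surv_mod <- (xs / xmin)^(1 - tau)
      ks <- max(abs(surv_mod - surv_emp))
    }
    if (tau <= 1) stop("estimated exponent <= 1: not a normalisable tail",
                       call. = FALSE)
    structure(list(exponent = tau, xmin = xmin, n_tail = n,
                   stderr = (tau - 1) / sqrt(n), ks = ks,
                   discrete = discrete, low_sample = n < 50),
              class = "wc_plfit")
  }
  out <- fit1(xmin)
  if (out$low_sample)
    warning("fewer than 50 tail samples: exponent estimate flagged unreliable",
            call. = FALSE)
  if (!is.null(xmin_sweep)) {
    sw <- do.call(rbind, lapply(xmin_sweep, function(xm) {
      f <- suppressWarnings(fit1(xm))
      data.frame(xmin = xm, exponent = f$exponent, stderr = f$stderr,
                 n_tail = f$n_tail, ks = f$ks)
    }))
    attr(out, "sweep") <- sw
  }
  out
}

#' @export
print.wc_plfit <- function(x, ...) {
  cat(sprintf(
    "Power-law MLE (%s): exponent = %.4f +/- %.4f (xmin = %g, n = %d, KS = %.4f)%s\n",
    if (x$discrete) "discrete" else "continuous", x$exponent, x$stderr,
    x$xmin, x$n_tail, x$ks, if (x$low_sample) "  [low-sample]" else ""))
  invisible(x)
}

#' @export
coef.wc_plfit <- function(object, ...) c(exponent = object$exponent)

#' @export
plot.wc_plfit <- function(x, data = NULL, ...) {
  if (is.null(data)) stop("pass the fitted sample as `data`", call. = FALSE)
  tail <- sort(data[data >= x$xmin])
  n <- length(tail)
  graphics::plot(tail, (n:1) / n, log = "xy", xlab = "x",
                 ylab = "P(X >= x)", pch = 16, cex = 0.4, ...)
  if (x$discrete) {
    xs <- sort(unique(round(tail)))
    graphics::lines(xs, hurwitz_zeta(x$exponent, xs) /
                      hurwitz_zeta(x$exponent, x$xmin), col = 2)
  } else {
    graphics::lines(tail, (tail / x$xmin)^(1 - x$exponent), col = 2)
  }
  invisible(x)
}

#' Avalanche size-duration scaling exponent
#'
#' Least-squares slope `gamma` of `log <S | T>` versus `log T` over the
#' durations falling in the fitting window, where `<S | T>` is the mean
#' avalanche size at duration `T`. Also reports the crackling-noise
#' prediction `gamma_pred = (tau_T - 1) / (tau_S - 1)` when the two
#' distribution fits are supplied (2 for the branching-process values
#' `tau_S = 3/2`, `tau_T = 2`).
#'
#' @param catalog An `avalanche_catalog`.
#' @param window `c(Tlo, Thi)` duration window (same units as durations).
#' @param size_fit,duration_fit Optional `wc_plfit` objects for the
#'   crackling-noise prediction.
#' @param weights `"none"` (plain least squares) or `"counts"` (weight each
#'   duration's mean size by its avalanche count; appropriate when counts
#'   per duration are small and heteroscedastic).
#' @return List with `gamma`, `n_durations`, `fit` (the `lm`),
#'   `gamma_pred` (or `NA`).
#' @export
size_duration_scaling <- function(catalog, window, size_fit = NULL,
                                  duration_fit = NULL,
                                  weights = c("none", "counts")) {
  stopifnot(inherits(catalog, "avalanche_catalog"))
  weights <- match.arg(weights)
  mS <- tapply(catalog$size, catalog$duration, mean)
  nT <- as.numeric(table(catalog$duration))
  Tu <- as.numeric(names(mS))
  keep <- Tu >= window[1] & Tu <= window[2]
  if (sum(keep) < 2)
    stop("fewer than 2 distinct durations in the fitting window", call. = FALSE)
  w <- if (weights == "counts") nT[keep] else NULL
  fit <- stats::lm(log(as.numeric(mS[keep])) ~ log(Tu[keep]), weights = w)
  gpred <- NA_real_
  if (!is.null(size_fit) && !is.null(duration_fit))
    gpred <- (duration_fit$exponent - 1) / (size_fit$exponent - 1)
  list(gamma = unname(stats::coef(fit)[2]), n_durations = sum(keep),
       fit = fit, gamma_pred = gpred)
}

#' Mean avalanche temporal profiles and shape collapse
#'
#' For each duration class (avalanches of `T` bins), computes the mean
#' spike count per bin as a function of rescaled time `t/T`, then rescales
#' the profiles as `s(t, T) * T^(1 - gamma)`; at criticality the rescaled
#' curves collapse onto a single universal (and in this model markedly
#' asymmetric) scaling function. Collapse quality is the variance across
#' duration classes of the rescaled curves, interpolated on a common
#' `t/T` grid and normalised by the squared mean curve.
#'
#' @param catalog A binned `avalanche_catalog` with stored profiles.
#' @param durations Integer vector of duration classes to use (in bins).
#' @param gamma Size-duration scaling exponent used for the collapse.
#' @param min_count Duration classes with fewer avalanches are skipped
#'   (with a warning).
#' @param grid_n Number of points of the common rescaled-time grid.
#' @return List with `profiles` (per-class mean profile at rescaled time),
#'   `collapse_quality` and `mean_shape` (common-grid average of the
#'   rescaled curves).
#' @export
avalanche_shape <- function(catalog, durations, gamma = 2, min_count = 20,
                            grid_n = 50) {
  prof <- attr(catalog, "profiles")
  if (is.null(prof))
    stop("catalog has no stored profiles (detect with `profiles = TRUE`)",
         call. = FALSE)
  delta <- attr(catalog, "meta")$delta
  if (is.null(delta)) delta <- 1          # durations already in bin counts
  nb <- round(catalog$duration / delta)
  out <- list()
  for (Tn in durations) {
    idx <- which(nb == Tn)
    if (length(idx) < min_count) {
      warning(sprintf("duration class %d skipped: only %d avalanches", Tn,
                      length(idx)), call. = FALSE)
      next
    }
    m <- colMeans(do.call(rbind, prof[idx]))
    out[[as.character(Tn)]] <- list(T = Tn, n = length(idx),
                                    t_rescaled = (seq_len(Tn) - 0.5) / Tn,
                                    mean_profile = m,
                                    rescaled = m * Tn^(1 - gamma))
  }
  if (length(out) < 2)
    stop("need at least 2 usable duration classes for a collapse", call. = FALSE)
  grid <- seq(0.025, 0.975, length.out = grid_n)
  curves <- vapply(out, function(cl)
    stats::approx(cl$t_rescaled, cl$rescaled, xout = grid, rule = 2)$y,
    numeric(grid_n))
  mshape <- rowMeans(curves)
  quality <- mean(apply(curves, 1, stats::var)) / mean(mshape)^2
  list(profiles = out, collapse_quality = quality,
       mean_shape = data.frame(t = grid, value = mshape))
}
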