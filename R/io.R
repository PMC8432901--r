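# Plain-text readers and writers for the three data products (event
# streams, rate time series, avalanche catalogs) and a config-driven
# pipeline runner. All files are delimited text with `#key value` header
# lines so they round-trip losslessly, including metadata.

write_header <- function(con, meta) {
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (length(v) && !is.na(v[1]))
      writeLines(sprintf("#%s %s", nm, paste(format(v, digits = 17),
                                             collapse = " ")), con)
  }
}

read_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in hdr) {
    parts <- strsplit(sub("^#", "", ln), "[ \t]+")[[1]]
    out[[parts[1]]] <- parts[-1]
  }
  out
}

params_meta <- function(p) {
  list(alpha = p$alpha, beta = p$beta, w_E = p$w_E, w_I = p$w_I, h = p$h,
       N = p$N)
}

params_from_meta <- function(meta) {
  wc_params(alpha = as.numeric(meta$alpha[1]), beta = as.numeric(meta$beta[1]),
            w_E = as.numeric(meta$w_E[1]), w_I = as.numeric(meta$w_I[1]),
            h = as.numeric(meta$h[1]), N = as.numeric(meta$N[1]))
}

#' Write / read a spike event stream
#'
#' Text format: `#param` header lines (`alpha`, `beta`, `w_E`, `w_I`,
#' `h`, `N`, `seed`, `initial k l`, `t0`, `t_end`), then one row
#' `t_ms pop delta` per event with `pop` in `{E, I}` and `delta` in
#' `{+1, -1}`. Event times must be non-decreasing; violations are
#' rejected on read.
#'
#' @param stream A `wc_event_stream`.
#' @param path File path.
#' @return `write_event_stream` returns `path` invisibly;
#'   `read_event_stream` returns a `wc_event_stream`.
#' @export
write_event_stream <- function(stream, path) {
  stopifnot(inherits(stream, "wc_event_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, c(params_meta(stream$params),
                      list(seed = stream$seed,
                           initial = c(stream$initial_state[["k"]],
                                       stream$initial_state[["l"]]),
                           t0 = stream$t0, t_end = stream$t_end)))
  ev <- stream$events
  writeLines(sprintf("%.17g\t%s\t%+d", ev$t, as.character(ev$pop), ev$delta),
             con)
  invisible(path)
}

#' @rdname write_event_stream
#' @export
read_event_stream <- function(path) {
  lines <- readLines(path)
  meta <- read_header(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad))
      stop(sprintf("parse error at data row %d: expected 3 fields", bad[1]),
           call. = FALSE)
    t <- as.numeric(vapply(parts, `[`, "", 1))
    pop <- vapply(parts, `[`, "", 2)
    delta <- as.integer(vapply(parts, `[`, "", 3))
    if (anyNA(t) || anyNA(delta) || !all(pop %in% c("E", "I")))
      stop("parse error: malformed event row", call. = FALSE)
    if (any(diff(t) < 0))
      stop("validation error: event times must be non-decreasing", call. = FALSE)
  } else {
    t <- numeric(0); pop <- character(0); delta <- integer(0)
  }
  new_event_stream(t, pop, delta,
                   init = c(k = as.integer(meta$initial[1]),
                            l = as.integer(meta$initial[2])),
                   params = params_from_meta(meta),
                   seed = if (is.null(meta$seed)) NA else
                     suppressWarnings(as.numeric(meta$seed[1])),
                   t0 = as.numeric(meta$t0[1]), t_end = as.numeric(meta$t_end[1]))
}

#' Write / read a rate time series
#'
#' Text format: header lines with the model parameters and the sampling
#' grid (`t0`, `dt_sample`), then rows `t_ms k l R_per_ms`.
#'
#' @param series A `wc_rate_series`.
#' @param path File path.
#' @return `write_series` returns `path` invisibly; `read_series` a
#'   `wc_rate_series`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "wc_rate_series"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(t0 = series$t0, dt_sample = series$dt_sample)
  if (!is.null(series$params)) meta <- c(params_meta(series$params), meta)
  write_header(con, meta)
  tt <- series_time(series)
  k <- if (is.null(series$k)) rep(NA_real_, length(tt)) else series$k
  l <- if (is.null(series$l)) rep(NA_real_, length(tt)) else series$l
  writeLines(sprintf("%.17g\t%.17g\t%.17g\t%.17g", tt, k, l, series$R), con)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  meta <- read_header(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  m <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
              ncol = 4, byrow = TRUE)
  p <- if (!is.null(meta$alpha)) params_from_meta(meta) else NULL
  out <- structure(list(t0 = as.numeric(meta$t0[1]),
                        dt_sample = as.numeric(meta$dt_sample[1]),
                        k = m[, 2], l = m[, 3], R = m[, 4], params = p),
                   class = "wc_rate_series")
  if (all(is.na(out$k))) { out$k <- NULL; out$l <- NULL }
  out
}

#' Write / read an avalanche catalog
#'
#' Text format: `#method`, detector metadata, then rows
#' `size duration_ms`.
#'
#' @param catalog An `avalanche_catalog`.
#' @param path File path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` an
#'   `avalanche_catalog` (profiles are not serialised).
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "avalanche_catalog"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(catalog, "meta")
  write_header(con, c(list(method = attr(catalog, "method")), meta))
  writeLines(sprintf("%.17g\t%.17g", catalog$size, catalog$duration), con)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  meta <- read_header(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body)) {
    m <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
                ncol = 2, byrow = TRUE)
  } else m <- matrix(numeric(0), ncol = 2)
  method <- meta$method[1]
  meta$method <- NULL
  new_catalog(m[, 1], m[, 2], method,
              lapply(meta, function(v) as.numeric(v[1])))
}

#' Analysis configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are
#' rejected. The configuration round-trips losslessly through YAML
#' (`yaml::write_yaml` / [read_config()]).
#'
#' @param model Named list of [wc_params()] arguments.
#' @param engine `"gillespie"` or `"langevin"`.
#' @param t_max,dt,dt_sample,seed,burn_in Engine settings (ms / integer).
#' @param stages Character subset of
#'   `c("analytic", "simulate", "avalanches", "correlate")`.
#' @param delta Bin widths (ms) for binned avalanche detection.
#' @param theta_rule `"zero"`, `"mean"`, or a number (threshold in ms^-1).
#' @param size_def Threshold-avalanche size definition (1, 2 or 3).
#' @param s_min,t_min Lower fitting bounds for the size and duration
#'   power-law fits.
#' @param max_lag,corr_window Correlation settings (ms; window as
#'   fractions of the peak).
#' @return A validated `wc_config` list.
#' @export
wc_config <- function(model = list(), engine = "gillespie", t_max = 1e5,
                      dt = 1e-3, dt_sample = 1, seed = 1, burn_in = NULL,
                      stages = c("analytic", "simulate", "avalanches",
                                 "correlate"),
                      delta = 1, theta_rule = "zero", size_def = 2,
                      s_min = 10, t_min = 10, max_lag = 500,
                      corr_window = c(0.01, 0.2)) {
  allowed_model <- c("alpha", "beta", "w_E", "w_I", "w0", "w_sum", "h", "N")
  unknown <- setdiff(names(model), allowed_model)
  if (length(unknown))
    stop("unknown model keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  engine <- match.arg(engine, c("gillespie", "langevin"))
  if (!(identical(theta_rule, "zero") || identical(theta_rule, "mean") ||
        is.numeric(theta_rule)))
    stop("`theta_rule` must be \"zero\", \"mean\" or a number", call. = FALSE)
  structure(list(model = model, engine = engine, t_max = t_max, dt = dt,
                 dt_sample = dt_sample, seed = seed, burn_in = burn_in,
                 stages = stages, delta = delta, theta_rule = theta_rule,
                 size_def = size_def, s_min = s_min, t_min = t_min,
                 max_lag = max_lag, corr_window = corr_window),
            class = "wc_config")
}

#' @rdname wc_config
#' @param path YAML file written by `yaml::write_yaml(unclass(config), path)`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(wc_config, raw)
}

#' Write a pipeline report as JSON
#'
#' Serialises a [run_pipeline()] report (or any nested list of scalars) to
#' JSON at full numeric precision.
#'
#' @param report A report list.
#' @param path Output path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order -- `analytic` (fixed point,
#' relaxation times, linear-noise firing-rate statistics), `simulate`
#' (Gillespie or Langevin run), `avalanches` (zero-/finite-threshold
#' detection and power-law fits, size-duration scaling) and `correlate`
#' (empirical autocorrelation and correlation-time fit) -- and returns a
#' machine-readable report embedding the resolved configuration and seed.
#' Identical configurations (including seed) yield identical reports.
#'
#' @param config A [wc_config()].
#' @return Named list report: `config`, `analytic` (`sigma0`, `r0_Hz`,
#'   `tau1`, `tau2`, `w0c`, `sigma_RR`, `cv2`), and per-stage results
#'   (`simulate`: stationary moments; `avalanches`: fitted `tau_S`,
#'   `tau_T`, `gamma`; `correlate`: `tau_max`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "wc_config"))
  p <- do.call(wc_params, config$model)
  report <- list(config = unclass(config))
  if ("analytic" %in% config$stages) {
    fp <- stable_fixed_point(p)
    an <- list(sigma0 = fp$sigma0, r0_Hz = fp$r0_Hz, tau1 = fp$tau1,
               tau2 = fp$tau2, w0c = critical_coupling(p))
    st <- tryCatch({
      sol <- wc_linear_noise(p)
      rate_statistics(sol)
    }, error = function(e) NULL)
    if (!is.null(st)) {
      an$sigma_RR <- st$sigma_RR; an$fano <- st$fano; an$cv2 <- st$cv2
    }
    report$analytic <- an
  }
  sim <- NULL
  if (any(c("simulate", "avalanches", "correlate") %in% config$stages)) {
    rec <- c("series", if ("avalanches" %in% config$stages) "bins")
    sim <- if (config$engine == "gillespie")
      wc_gillespie(p, t_max = config$t_max, seed = config$seed,
                   record = rec, dt_sample = config$dt_sample,
                   delta_bin = min(config$delta), burn_in = config$burn_in)
    else
      wc_langevin(p, t_max = config$t_max, dt = config$dt,
                  seed = config$seed, record = "series",
                  dt_sample = config$dt_sample, burn_in = config$burn_in)
    report$simulate <- sim$moments
    report$simulate$n_events <- sim$n_events
  }
  if ("avalanches" %in% config$stages) {
    theta <- switch(as.character(config$theta_rule[1]),
                    zero = 0, mean = sim$moments$mean_rate,
                    as.numeric(config$theta_rule))
    cat_th <- detect_threshold(sim$series, theta = theta,
                               size_def = config$size_def)
    av <- list(theta = theta, n_avalanches = nrow(cat_th))
    if (sum(cat_th$size >= config$s_min) >= 50) {
      fS <- fit_power_law(cat_th$size, xmin = config$s_min)
      av$tau_S <- fS$exponent; av$tau_S_se <- fS$stderr
    }
    if (sum(cat_th$duration >= config$t_min) >= 50) {
      fT <- fit_power_law(cat_th$duration, xmin = config$t_min)
      av$tau_T <- fT$exponent; av$tau_T_se <- fT$stderr
    }
    if (!is.null(sim$bins)) {
      cat_b <- detect_binned(sim, delta = min(config$delta))
      gam <- tryCatch(
        size_duration_scaling(cat_b, window = c(80, 200))$gamma,
        error = function(e) NA_real_)
      av$gamma <- gam
    }
    report$avalanches <- av
  }
  if ("correlate" %in% config$stages) {
    co <- empirical_autocorrelation(sim$series, max_lag = config$max_lag)
    ct <- tryCatch(fit_correlation_time(co, window = config$corr_window),
                   error = function(e) list(tau_max = NA_real_))
    report$correlate <- list(tau_max = ct$tau_max)
  }
  report
}
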