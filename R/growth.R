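# Lag-phase estimation from microbial growth curves and the relative lag
# increase under peroxide doses -- the growth-retardation statistic.

#' Simulate dose-dependent lagged-logistic growth curves
#'
#' OD stays at the baseline until the dose-specific lag, then rises
#' logistically at rate `mu_max` toward the carrying capacity; additive
#' Gaussian noise is applied and OD clamped at zero. A dose whose lag is
#' `NA` is a "no growth" dose and yields a flat baseline.
#'
#' @param lag_by_dose named numeric vector: dose (mM) -> lag (h); `NA` marks
#'   no detectable growth at that dose.
#' @param mu_max maximum specific growth rate (1/h, > 0).
#' @param carrying_capacity plateau OD.
#' @param baseline_od inoculation OD (> 0).
#' @param duration total sampled time (h).
#' @param sampling_interval time between OD reads (h, > 0).
#' @param n_replicates replicate curves per dose.
#' @param noise_sd OD noise standard deviation.
#' @param strain strain label attached to every curve.
#' @param seed integer seed.
#' @return object of class `growth_curve_set`: list with `curves`
#'   (data.frame: time_h, od, dose_mM, strain, replicate) and
#'   `true_lag_by_dose`.
#' @export
simulate_growth_curves <- function(lag_by_dose, mu_max = 0.8,
                                   carrying_capacity = 1.0,
                                   baseline_od = 0.02, duration = 16,
                                   sampling_interval = 1 / 6,
                                   n_replicates = 3L, noise_sd = 0.005,
                                   strain = "WT", seed = 0L) {
  mu_max <- .check_number(mu_max, "mu_max", min = 1e-9)
  sampling_interval <- .check_number(sampling_interval, "sampling_interval",
                                     min = 1e-9)
  noise_sd <- .check_number(noise_sd, "noise_sd", min = 0)
  if (is.null(names(lag_by_dose))) stop("lag_by_dose must be named by dose",
                                        call. = FALSE)
  if (any(lag_by_dose < 0, na.rm = TRUE)) stop("lags must be >= 0", call. = FALSE)
  tt <- seq(0, duration, by = sampling_interval)
  set.seed(.derive_seed(seed, paste0("growth", strain)))
  rows <- list()
  for (d in names(lag_by_dose)) {
    lag <- lag_by_dose[[d]]
    for (r in seq_len(n_replicates)) {
      if (is.na(lag)) {
        od <- rep(baseline_od, length(tt))
      } else {
        od <- ifelse(
          tt <= lag, baseline_od,
          carrying_capacity /
            (1 + ((carrying_capacity - baseline_od) / baseline_od) *
               exp(-mu_max * (tt - lag))))
      }
      if (noise_sd > 0) od <- pmax(od + rnorm(length(tt), sd = noise_sd), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        time_h = tt, od = od, dose_mM = as.numeric(d), strain = strain,
        replicate = paste0("r", r), stringsAsFactors = FALSE)
    }
  }
  structure(list(curves = do.call(rbind, rows),
                 true_lag_by_dose = lag_by_dose,
                 sampling_interval = sampling_interval),
            class = "growth_curve_set")
}

#' Write / read growth curves as TSV
#'
#' Columns: `time_h`, `od`, `dose_mM`, `strain`, `replicate`.
#'
#' @param x a `growth_curve_set` or a curves data.frame.
#' @param path TSV path.
#' @export
write_growth <- function(x, path) {
  curves <- if (inherits(x, "growth_curve_set")) x$curves else x
  write.table(curves, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth
#' @export
read_growth <- function(path) {
  read.delim(path, colClasses = c(strain = "character", replicate = "character"))
}

#' Estimate the lag phase of one growth curve
#'
#' The tangent method fits a sliding-window regression to `log(OD)` versus
#' time, takes the window of maximum slope (the maximum specific growth
#' rate), and returns the time at which that tangent crosses the baseline
#' `log(OD)` level. The threshold method returns the first time OD exceeds
#' `baseline + delta`. A curve whose total rise above baseline stays below
#' `delta_min` is a no-growth curve (lag undefined).
#'
#' @param time,od numeric vectors (time in h, strictly increasing; OD >= 0),
#'   or a data.frame with columns `time_h` and `od` as first argument.
#' @param method `"tangent"` (default) or `"threshold"`.
#' @param window points per regression window (tangent method).
#' @param delta OD rise defining the threshold crossing.
#' @param delta_min minimum OD rise to call growth at all.
#' @param baseline_points number of initial points whose median defines the
#'   baseline.
#' @return object of class `lag_estimate`: list with `lag` (h, NA when no
#'   growth), `mu_max` (1/h, tangent slope; NA for threshold/no growth),
#'   `max_od`, `baseline`, `no_growth`, `method`.
#' @export
estimate_lag <- function(time, od = NULL, method = c("tangent", "threshold"),
                         window = 9L, delta = 0.02, delta_min = 0.05,
                         baseline_points = 6L) {
  method <- match.arg(method)
  if (is.data.frame(time)) {
    od <- time$od
    time <- time$time_h
  }
  if (length(time) < 5L) stop("need >= 5 time points", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (any(od < 0)) stop("OD must be >= 0", call. = FALSE)
  baseline <- median(od[seq_len(min(baseline_points, length(od)))])
  res <- function(lag, mu = NA_real_, none = FALSE) {
    structure(list(lag = lag, mu_max = mu, max_od = max(od),
                   baseline = baseline, no_growth = none, method = method),
              class = "lag_estimate")
  }
  if (max(od) - baseline < delta_min) return(res(NA_real_, none = TRUE))
  if (method == "threshold") {
    i <- which(od > baseline + delta)[1L]
    return(res(time[i]))
  }
  y <- log(pmax(od, 1e-9))
  n <- length(y)
  window <- max(3L, min(window, n))
  # only fit tangents where the signal is clearly above the baseline: near
  # the baseline the log of the measurement noise dominates the slope
  clear <- od >= baseline + delta
  starts <- which(vapply(seq_len(n - window + 1L), function(i)
    all(clear[i:(i + window - 1L)]), TRUE))
  if (length(starts) == 0L) starts <- seq_len(n - window + 1L)
  best <- NULL
  for (i in starts) {
    idx <- i:(i + window - 1L)
    tx <- time[idx]; ty <- y[idx]
    b <- sum((tx - mean(tx)) * (ty - mean(ty))) / sum((tx - mean(tx))^2)
    if (is.null(best) || b > best$b) {
      best <- list(b = b, a = mean(ty) - b * mean(tx))
    }
  }
  if (best$b <= 0) return(res(NA_real_, none = TRUE))
  lag <- (log(max(baseline, 1e-9)) - best$a) / best$b
  res(max(lag, 0), mu = best$b)
}

#' @export
print.lag_estimate <- function(x, ...) {
  if (x$no_growth) {
    cat("lag_estimate: no detectable growth (max OD",
        format(x$max_od, digits = 3), ")\n")
  } else {
    cat("lag_estimate:", format(x$lag, digits = 4), "h",
        if (!is.na(x$mu_max)) paste0("(mu_max ", format(x$mu_max, digits = 3),
                                     " 1/h)"), "\n")
  }
  invisible(x)
}

#' Relative lag increase of a treated curve over its control
#'
#' `(lag_treated - lag_control) / lag_control`. A no-growth treated curve
#' has no defined increase and returns `NA` flagged `no_growth` -- the
#' "missing bar" semantics of a dose at which a strain fails to grow.
#'
#' @param treated,control `lag_estimate` objects.
#' @return numeric fraction, or `NA` with attribute `no_growth = TRUE`.
#' @export
relative_lag_increase <- function(treated, control) {
  stopifnot(inherits(treated, "lag_estimate"), inherits(control, "lag_estimate"))
  if (control$no_growth) stop("control shows no growth", call. = FALSE)
  if (control$lag <= 0) stop("control lag must be > 0", call. = FALSE)
  if (treated$no_growth) {
    out <- NA_real_
    attr(out, "no_growth") <- TRUE
    return(out)
  }
  (treated$lag - control$lag) / control$lag
}

#' Dose-response summary of relative lag increases
#'
#' Estimates the lag of every curve, references each strain's replicates to
#' that strain's mean zero-dose lag, and summarizes per strain and dose.
#' Strains without a zero-dose control are dropped with a warning.
#'
#' @param curves data.frame with columns `time_h`, `od`, `dose_mM`,
#'   `strain`, `replicate` (or a `growth_curve_set`).
#' @param ... passed to [estimate_lag()].
#' @return data.frame with per (strain, dose): `mean_rel_increase`,
#'   `sd_rel_increase`, `n`, `no_growth_fraction`.
#' @export
dose_response_table <- function(curves, ...) {
  if (inherits(curves, "growth_curve_set")) curves <- curves$curves
  out <- list()
  for (s in unique(curves$strain)) {
    cs <- curves[curves$strain == s, , drop = FALSE]
    doses <- sort(unique(cs$dose_mM))
    if (!0 %in% doses) {
      warning("strain ", s, " has no zero-dose control; dropped", call. = FALSE)
      next
    }
    est <- list()
    for (d in doses) {
      cd <- cs[cs$dose_mM == d, , drop = FALSE]
      est[[as.character(d)]] <- lapply(split(cd, cd$replicate), estimate_lag, ...)
    }
    ctrl <- est[["0"]]
    ctrl_lags <- vapply(ctrl, function(e) if (e$no_growth) NA_real_ else e$lag, 0)
    if (all(is.na(ctrl_lags))) {
      warning("strain ", s, " shows no growth at zero dose; dropped",
              call. = FALSE)
      next
    }
    ctrl_mean <- structure(list(lag = mean(ctrl_lags, na.rm = TRUE),
                                no_growth = FALSE), class = "lag_estimate")
    for (d in doses) {
      rel <- vapply(est[[as.character(d)]], function(e)
        as.numeric(relative_lag_increase(e, ctrl_mean)), 0)
      ng <- vapply(est[[as.character(d)]], function(e) e$no_growth, TRUE)
      out[[length(out) + 1L]] <- data.frame(
        strain = s, dose_mM = d,
        mean_rel_increase = if (all(ng)) NA_real_ else mean(rel, na.rm = TRUE),
        sd_rel_increase = if (sum(!ng) >= 2L) sd(rel, na.rm = TRUE) else NA_real_,
        n = length(rel), no_growth_fraction = mean(ng),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no strain with a usable zero-dose control",
                              call. = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
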