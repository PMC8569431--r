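#' Estimate the maximum specific growth rate from an OD time series
#'
#' Fits a cubic smoothing spline to log OD against time and takes the maximum
#' of its first derivative as the specific growth rate estimate (min^-1).
#' Because the measurement noise is additive on OD, log OD is
#' heteroscedastic; a first-stage spline on raw OD supplies fitted densities
#' that (a) decide which samples clear the quantification floor -- the larger
#' of `min_od` and 5 times the estimated instrument noise -- without the
#' selection bias of thresholding noisy readings directly, and (b) provide
#' OD^2 weights (the delta-method precision of log OD) for the second-stage
#' log-OD spline. Smoothing is chosen by generalized cross-validation with a
#' floor on the smoothing parameter so measurement noise is never
#' interpolated; the parameter actually used is recorded for provenance.
#' Only the first `window_min` minutes of the series enter the fit, and the
#' saturated tail beyond `trim_saturation` of the observed log-OD range is
#' discarded so the stationary phase cannot drag the cross-validated
#' bandwidth away from the growth peak.
#'
#' @param curve data frame with columns `time_min` and `od830` (at least 10
#'   points, strictly increasing times, positive OD).
#' @param smoothing `"auto"` for GCV with the floor, or a numeric `spar`
#'   passed straight to [stats::smooth.spline()].
#' @param window_min analysis window from the first sample (min).
#' @param spar_floor lower bound on the GCV-chosen smoothing parameter.
#' @param min_od quantification floor: samples below this OD are dropped
#'   before the log transform, since readings near the instrument noise floor
#'   carry no usable log-scale information.
#' @param trim_saturation fraction of the observed log-OD range beyond which
#'   trailing samples are dropped (`NULL` keeps the full window).
#' @param log_od if `FALSE`, the derivative is taken on raw OD instead
#'   (units then OD/min, not min^-1); provided for comparison only.
#' @return object of class `growth_rate_estimate`: list with `mu_max`,
#'   `t_at_max`, `smoothing`, `method = "spline"`, `window_min` and
#'   `flag` (`"ok"`, `"flat"` or `"nonpositive"`).
#' @export
estimate_growth_rate <- function(curve, smoothing = "auto",
                                 window_min = 2500, spar_floor = 0.3,
                                 min_od = 0.005, trim_saturation = 0.95,
                                 log_od = TRUE) {
  curve <- validate_curve(curve)
  curve <- curve[curve$time_min <= curve$time_min[1] + window_min, ]
  if (nrow(curve) < 10)
    stop_config("fewer than 10 samples inside the analysis window")
  x <- curve$time_min
  od <- curve$od830

  if (stats::sd(od) < 1e-10 || stats::sd(log(od)) < 1e-10) {
    return(new_growth_estimate(0, x[1], NA_real_, "spline", window_min,
                               flag = "flat"))
  }
  # stage 1: raw-OD trend defines quantifiable samples and log-OD weights
  trend <- pmax(stats::predict(stats::smooth.spline(x, od, cv = FALSE), x)$y,
                1e-6)
  noise_hat <- stats::mad(diff(od)) / sqrt(2)
  keep <- trend >= max(min_od, 5 * noise_hat)
  if (sum(keep) < 10) keep <- rep(TRUE, length(x))
  x <- x[keep]
  y <- if (log_od) log(pmax(od[keep], 1e-6)) else od[keep]
  w <- if (log_od) trend[keep]^2 else rep(1, sum(keep))

  if (stats::sd(y) < 1e-10) {
    return(new_growth_estimate(0, x[1], NA_real_, "spline", window_min,
                               flag = "flat"))
  }
  if (!is.null(trim_saturation)) {
    cut_i <- which(y >= min(y) + trim_saturation * (max(y) - min(y)))[1]
    if (!is.na(cut_i) && cut_i >= 10) {
      x <- x[seq_len(cut_i)]; y <- y[seq_len(cut_i)]; w <- w[seq_len(cut_i)]
    }
  }
  if (identical(smoothing, "auto")) {
    fit <- stats::smooth.spline(x, y, w = w, cv = FALSE)
    if (fit$spar < spar_floor)
      fit <- stats::smooth.spline(x, y, w = w, spar = spar_floor)
  } else {
    fit <- stats::smooth.spline(x, y, w = w, spar = smoothing)
  }
  grid <- seq(min(x), max(x), length.out = max(length(x) * 2L, 200L))
  d1 <- stats::predict(fit, grid, deriv = 1)
  i <- which.max(d1$y)
  mu <- d1$y[i]
  if (!is.finite(mu)) stop_config("spline derivative is not finite")
  flag <- if (mu <= 0) "nonpositive" else "ok"
  if (flag == "nonpositive")
    warning("maximum log-OD derivative is non-positive (declining series?)",
            call. = FALSE)
  new_growth_estimate(mu, d1$x[i], fit$spar, "spline", window_min, flag)
}

new_growth_estimate <- function(mu_max, t_at_max, smoothing, method,
                                window_min, flag = "ok", params = NULL) {
  structure(list(mu_max = mu_max, t_at_max = t_at_max, smoothing = smoothing,
                 method = method, window_min = window_min, flag = flag,
                 params = params),
            class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf("<growth_rate_estimate> mu_max = %.5g min^-1 at t = %.0f min (%s%s)\n",
              x$mu_max, x$t_at_max, x$method,
              if (x$flag != "ok") paste0(", ", x$flag) else ""))
  invisible(x)
}

validate_curve <- function(curve) {
  if (!is.data.frame(curve) || !all(c("time_min", "od830") %in% names(curve)))
    stop_config("curve must be a data frame with time_min and od830 columns")
  if (nrow(curve) < 10) stop_config("growth curves need at least 10 samples")
  if (any(!is.finite(curve$od830)) || any(curve$od830 <= 0))
    stop_config("od830 must be finite and positive")
  if (is.unsorted(curve$time_min, strictly = TRUE))
    stop_config("time_min must be strictly increasing")
  curve
}

#' Fit the modified Gompertz growth model by nonlinear least squares
#'
#' Fits `log OD = y0 + A * exp(-exp(mu*e/A * (lag - t) + 1))` by
#' Levenberg-Marquardt least squares; `mu` is the maximum slope of log OD,
#' i.e. the same quantity the spline estimator targets, so the two serve as
#' mutual cross-checks. Initialization is deterministic: `mu` from the spline
#' estimate, `A` from the observed log-range, `lag` from the first time OD
#' exceeds twice its starting value.
#'
#' @inheritParams estimate_growth_rate
#' @return object of class `growth_rate_estimate` with `method =
#'   "gompertz"` and the fitted parameters in `$params`
#'   (`y0`, `A`, `mu`, `lag`).
#' @export
fit_gompertz <- function(curve, window_min = 2500, min_od = 0.005) {
  curve <- validate_curve(curve)
  curve <- curve[curve$time_min <= curve$time_min[1] + window_min, ]
  if (nrow(curve) < 10)
    stop_config("fewer than 10 samples inside the analysis window")
  od <- curve$od830
  if (stats::sd(od) > 1e-10) {
    # the global parametric fit keeps everything above the quantification
    # floor: low-density samples pin the lag and are softly discounted by the
    # precision weights anyway
    trend <- pmax(stats::predict(stats::smooth.spline(curve$time_min, od,
                                                      cv = FALSE),
                                 curve$time_min)$y, 1e-6)
    keep <- trend >= min_od
    if (sum(keep) >= 10) {
      curve <- curve[keep, , drop = FALSE]
      trend <- trend[keep]
    }
  } else trend <- od
  x <- curve$time_min
  y <- log(curve$od830)
  if (stats::sd(y) < 1e-10 || diff(range(y)) < 0.05)
    stop_config("Gompertz fit did not converge: curve has no usable growth signal")

  A0 <- max(diff(range(y)), 0.1)
  mu0 <- tryCatch(estimate_growth_rate(curve, window_min = window_min)$mu_max,
                  error = function(e) NA_real_)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- A0 / diff(range(x)) * 4
  lag0 <- x[which(y >= y[1] + log(2))[1]]
  if (is.na(lag0)) lag0 <- x[1] + diff(range(x)) / 4
  start <- list(y0 = y[1], A = A0, mu = mu0, lag = lag0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + A * exp(-exp(mu * exp(1) / A * (lag - x) + 1)),
      start = start, weights = trend^2,
      lower = c(y0 = -Inf, A = 1e-6, mu = 1e-9, lag = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_config("Gompertz fit did not converge (start: y0=%.3g A=%.3g mu=%.3g lag=%.3g): %s",
                  start$y0, start$A, start$mu, start$lag, conditionMessage(e)))
  p <- as.list(stats::coef(fit))
  new_growth_estimate(p$mu, p$lag + p$A / (p$mu * exp(1)), NA_real_,
                      "gompertz", window_min, params = p)
}
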