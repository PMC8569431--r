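#' Per-temperature growth parameters for one strain
#'
#' Bundles the modified-Gompertz growth parameters of a strain at each
#' culture temperature used in the experiment: the maximum specific growth
#' rate `mu_max` (min^-1, the maximum slope of log OD), the lag time
#' `lag` (min) and the carrying capacity `capacity` (asymptotic OD830).
#' An optional `carryover` term rescales `mu_max` at one temperature when the
#' previous temperature segment matched a given condition; this models
#' populations that have internalized a fluctuation regime, i.e. whose growth
#' at 15 degrees depends on prior exposure to 43 degrees.
#'
#' @param strain_id identifier.
#' @param mu_max named numeric vector of maximum specific growth rates
#'   (min^-1) with names among `"15"`, `"37"`, `"43"`; all > 0.
#' @param lag named numeric vector of lag times (min), same names; >= 0.
#' @param capacity named numeric vector of asymptotic OD830 values, same
#'   names; must exceed every switching threshold of the regime the strain is
#'   simulated under.
#' @param od_noise_sd additive Gaussian measurement noise on OD (OD units).
#' @param carryover optional list `list(temp =, prev =, factor =)`:
#'   multiply `mu_max[temp]` by `factor` whenever the previous segment ran at
#'   temperature `prev`.
#' @return an object of class `strain_params`.
#' @export
strain_params <- function(strain_id, mu_max, lag, capacity,
                          od_noise_sd = 0.002, carryover = NULL) {
  temps <- names(mu_max)
  if (is.null(temps) || !all(temps %in% c("15", "37", "43")))
    stop_config("mu_max must be named with temperatures among 15/37/43")
  if (!all(temps %in% names(lag)) || !all(temps %in% names(capacity)))
    stop_config("lag and capacity must cover the same temperatures as mu_max")
  if (any(mu_max <= 0)) stop_config("mu_max must be positive")
  if (any(lag < 0)) stop_config("lag must be non-negative")
  if (any(capacity <= 0)) stop_config("capacity must be positive")
  if (od_noise_sd < 0) stop_config("od_noise_sd must be non-negative")
  if (!is.null(carryover)) {
    stopifnot(all(c("temp", "prev", "factor") %in% names(carryover)))
    if (carryover$factor <= 0) stop_config("carryover factor must be positive")
  }
  structure(list(strain_id = strain_id, mu_max = mu_max, lag = lag,
                 capacity = capacity, od_noise_sd = od_noise_sd,
                 carryover = carryover),
            class = "strain_params")
}

#' Temperature-switching regime of the evolution experiment
#'
#' Three regimes alternate the culture between 15 and 43 degrees C within one
#' serial-passage cycle:
#' \describe{
#'   \item{slow}{one density-triggered switch per cycle, at OD830 0.25;}
#'   \item{fast}{three density-triggered switches per cycle, at OD830 0.15,
#'     0.30 and 0.45;}
#'   \item{random}{time-triggered switches with segment durations drawn
#'     uniformly from 3--5 h at 43 degrees and 5--15 h at 15 degrees, so that
#'     comparable generation numbers accrue at the slow-growing cold
#'     temperature.}
#' }
#' Cycles start at the temperature the previous cycle ended at
#' (start-temperature alternation), and end with a transfer to fresh medium
#' just before stationary phase.
#'
#' @param kind one of `"slow"`, `"fast"`, `"random"`.
#' @param switch_ods strictly increasing OD830 thresholds (periodic regimes).
#' @param random_durations list with elements `"43"` and `"15"`, each a
#'   2-vector of uniform duration bounds in hours (random regime).
#' @return an object of class `temperature_regime`.
#' @export
temperature_regime <- function(kind = c("slow", "fast", "random"),
                               switch_ods = NULL, random_durations = NULL) {
  kind <- match.arg(kind)
  if (kind == "slow") switch_ods <- switch_ods %||% 0.25
  if (kind == "fast") switch_ods <- switch_ods %||% c(0.15, 0.30, 0.45)
  if (kind == "random") {
    random_durations <- random_durations %||%
      list("43" = c(3, 5), "15" = c(5, 15))
    for (b in random_durations) {
      if (length(b) != 2 || any(b <= 0) || b[1] >= b[2])
        stop_config("random duration bounds must be positive with lower < upper")
    }
  } else {
    if (is.unsorted(switch_ods, strictly = TRUE))
      stop_config("switch_ods must be strictly increasing")
    if (any(switch_ods <= 0)) stop_config("switch_ods must be positive")
  }
  structure(list(kind = kind, switch_ods = switch_ods,
                 random_durations = random_durations),
            class = "temperature_regime")
}

other_temp <- function(temp) if (temp == 15) 43 else 15

# ---- modified Gompertz growth law (Zwietering parameterization) -----------
#
# In log OD the curve is y(t) = y0 + A * exp(-exp(mu*e/A * (lag - t) + 1)),
# where A = log(capacity / od0) is the remaining log-growth, mu is the
# maximum slope of log OD (the maximum specific growth rate, min^-1) and lag
# is the lag time. Written this way mu_max is directly the quantity the
# growth module estimates from the derivative of log OD.

#' Modified Gompertz optical density curve
#'
#' @param t time since segment start (min).
#' @param od0 starting OD (> 0).
#' @param A asymptotic log-growth `log(capacity/od0)` (> 0).
#' @param mu maximum specific growth rate (min^-1).
#' @param lag lag time (min).
#' @return OD at time `t`.
#' @export
gompertz_od <- function(t, od0, A, mu, lag) {
  od0 * exp(A * exp(-exp(mu * exp(1) / A * (lag - t) + 1)))
}

# Inverse of gompertz_od: exact time at which the noiseless curve reaches od
# target (NA if the target exceeds the asymptote od0 * exp(A)).
gompertz_time_to_od <- function(target, od0, A, mu, lag) {
  ylog <- log(target / od0)
  if (ylog <= 0) return(0)
  if (ylog >= A) return(NA_real_)
  b <- log(-log(ylog / A))
  lag - (b - 1) * A / (mu * exp(1))
}

#' Convert spectrophotometer transmittance to optical density
#'
#' Optical density is defined as `-log10(T)` for a transmittance fraction
#' `T`; a transmittance of 95 percent (the standard Biolog inoculation
#' density) corresponds to an OD of about 0.0223.
#'
#' @param transmittance fraction in (0, 1].
#' @return optical density (dimensionless), same length as the input.
#' @export
transmittance_to_od <- function(transmittance) {
  if (any(!is.finite(transmittance)) || any(transmittance <= 0) ||
      any(transmittance > 1))
    stop_config("transmittance must lie in (0, 1]")
  -log10(transmittance)
}
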