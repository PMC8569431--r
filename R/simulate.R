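#' Simulate one serial-passage cycle under a temperature-switching regime
#'
#' Grows a culture from its inoculum along the modified Gompertz curve in log
#' OD, switching temperature whenever the regime demands it: at the
#' density thresholds of the periodic regimes, or after uniformly drawn
#' segment durations in the random regime. At every switch the curve is
#' re-anchored so OD is continuous: remaining growth follows the new
#' temperature's parameters from the current density, with a configurable
#' secondary lag (0 by default, since post-shift lag behaviour is not
#' observable at this sampling resolution). The cycle ends with a transfer to
#' fresh medium when the noiseless OD reaches `stationary_frac` of the active
#' temperature's capacity -- a deterministic proxy for "just before
#' stationary phase". In the periodic regimes the transfer trigger is armed
#' only after the full switch schedule has run; in the random regime it ends
#' the cycle whenever it fires. Switch and transfer events are located
#' exactly by inverting the Gompertz curve, while OD is sampled on a fixed
#' 4-minute grid with additive Gaussian measurement noise truncated at a
#' positive floor.
#'
#' @param strain a [strain_params()] object.
#' @param regime a [temperature_regime()] object.
#' @param start_temp temperature (15 or 43) the cycle begins at.
#' @param inoculum_od starting OD830 after dilution (> 0).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param culture_id,cycle identifiers carried into the output.
#' @param start_time_min global time offset of the cycle start (min).
#' @param prev_temp temperature of the segment that preceded the cycle (for
#'   carryover effects); defaults to `start_temp`, which is what
#'   start-temperature alternation implies.
#' @param dt_min sampling interval (min); the instrument reads every 4 min.
#' @param dilution_factor culture-volume ratio per transfer; 100 uL into
#'   20 mL gives (20 + 0.1)/0.1 = 201.
#' @param stationary_frac fraction of capacity that triggers the transfer.
#' @param secondary_lag lag (min) applied to post-switch segments.
#' @param noise_floor lower truncation of noisy OD readings.
#' @param max_minutes guard against unreachable thresholds.
#' @return an object of class `od_trajectory`: a list with `samples`
#'   (time_min, od830, od830_true, temperature_C), `events` (switch and
#'   transfer times with the exact noiseless OD), `segments` (per-segment
#'   boundaries and ODs, used for generation accounting), and scalar
#'   metadata.
#' @export
simulate_cycle <- function(strain, regime, start_temp,
                           inoculum_od = 0.0025, seed = NULL,
                           culture_id = strain$strain_id, cycle = 1L,
                           start_time_min = 0, prev_temp = start_temp,
                           dt_min = 4, dilution_factor = 201,
                           stationary_frac = 0.95, secondary_lag = 0,
                           noise_floor = 1e-4, max_minutes = 60 * 24 * 30) {
  stopifnot(inherits(strain, "strain_params"),
            inherits(regime, "temperature_regime"))
  if (!is.finite(inoculum_od) || inoculum_od <= 0)
    stop_config("inoculum OD must be positive")
  if (!start_temp %in% c(15, 43))
    stop_config("evolution cycles run at 15 or 43 degrees C")
  if (regime$kind != "random") {
    for (tm in c("15", "43")) {
      if (strain$capacity[[tm]] * stationary_frac <= max(regime$switch_ods))
        stop_config(
          "capacity at %s C (%.3g) does not exceed the largest switching threshold (%.3g)",
          tm, strain$capacity[[tm]], max(regime$switch_ods))
    }
    if (inoculum_od >= min(regime$switch_ods))
      stop_config("inoculum OD must lie below the first switching threshold")
  }

  run <- function() {
    temp <- start_temp
    prev <- prev_temp
    t_now <- 0
    od_now <- inoculum_od
    k <- 1L # index of the next scheduled switch
    n_sw <- if (regime$kind == "random") NA_integer_ else length(regime$switch_ods)
    seg <- list(); ev <- list()
    seg_i <- 0L
    repeat {
      seg_i <- seg_i + 1L
      tm <- as.character(temp)
      mu <- strain$mu_max[[tm]]
      co <- strain$carryover
      if (!is.null(co) && co$temp == temp && co$prev == prev) mu <- mu * co$factor
      K <- strain$capacity[[tm]]
      lag <- if (seg_i == 1L) strain$lag[[tm]] else secondary_lag
      A <- log(K / od_now)
      sat_od <- stationary_frac * K
      t_sat <- if (od_now >= sat_od) 0 else
        gompertz_time_to_od(sat_od, od_now, A, mu, lag)

      if (regime$kind == "random") {
        dur <- stats::runif(1, regime$random_durations[[tm]][1] * 60,
                            regime$random_durations[[tm]][2] * 60)
        ends_cycle <- !is.na(t_sat) && t_sat <= dur
        t_end <- if (ends_cycle) t_sat else dur
      } else if (k <= n_sw) {
        if (A <= 0 || regime$switch_ods[k] >= K)
          stop_config("culture cannot reach threshold %.3g at %s C",
                      regime$switch_ods[k], tm)
        t_end <- gompertz_time_to_od(regime$switch_ods[k], od_now, A, mu, lag)
        ends_cycle <- FALSE
        k <- k + 1L
      } else {
        t_end <- t_sat
        ends_cycle <- TRUE
      }
      if (is.na(t_end) || t_now + t_end > max_minutes)
        stop_config("cycle exceeded %d minutes before its transfer trigger",
                    max_minutes)
      od_end <- gompertz_od(t_end, od_now, A, mu, lag)
      seg[[seg_i]] <- data.frame(
        segment = seg_i, temperature_C = temp,
        t_start = t_now, t_end = t_now + t_end,
        od_start = od_now, od_end = od_end,
        mu_effective = mu, A = A, lag = lag)
      ev[[seg_i]] <- data.frame(
        time_min = t_now + t_end,
        kind = if (ends_cycle) "transfer" else "switch",
        od830 = od_end, temp_from = temp,
        temp_to = if (ends_cycle) NA_real_ else other_temp(temp))
      if (ends_cycle) break
      prev <- temp
      temp <- other_temp(temp)
      t_now <- t_now + t_end
      od_now <- od_end
    }
    segments <- do.call(rbind, seg)
    events <- do.call(rbind, ev)

    t_final <- segments$t_end[nrow(segments)]
    grid <- seq(0, t_final, by = dt_min)
    idx <- findInterval(grid, segments$t_start)
    od_true <- gompertz_od(grid - segments$t_start[idx],
                           segments$od_start[idx], segments$A[idx],
                           segments$mu_effective[idx], segments$lag[idx])
    od_noisy <- pmax(od_true + stats::rnorm(length(grid), 0, strain$od_noise_sd),
                     noise_floor)
    samples <- data.frame(
      time_min = start_time_min + grid,
      od830 = od_noisy, od830_true = od_true,
      temperature_C = segments$temperature_C[idx])
    segments$t_start <- segments$t_start + start_time_min
    segments$t_end <- segments$t_end + start_time_min
    events$time_min <- events$time_min + start_time_min

    structure(list(
      culture_id = culture_id, cycle = cycle, regime = regime$kind,
      samples = samples, events = events,
      segments = segments[, c("segment", "temperature_C", "t_start", "t_end",
                              "od_start", "od_end")],
      dilution_factor = dilution_factor,
      start_temp = start_temp, end_temp = segments$temperature_C[nrow(segments)],
      start_od = inoculum_od, end_od = segments$od_end[nrow(segments)]),
      class = "od_trajectory")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.od_trajectory <- function(x, ...) {
  cat(sprintf("<od_trajectory> %s cycle %d (%s regime): %d samples, %d switches, %.0f min\n",
              x$culture_id, x$cycle, x$regime, nrow(x$samples),
              sum(x$events$kind == "switch"),
              max(x$samples$time_min) - min(x$samples$time_min)))
  invisible(x)
}

#' Simulate a full fluctuating-temperature evolution experiment
#'
#' Runs `simulate_cycle()` for every population of a factorial design
#' (lineages x regimes x replicates) over `n_cycles` serial-passage cycles.
#' Each cycle starts at the temperature the previous cycle ended at and is
#' seeded with the previous end density divided by the dilution factor, so
#' the whole experiment is one continuous simulated lineage per population.
#' Every population draws from its own seed stream derived from the
#' top-level seed, so the output is reproducible and insensitive to design
#' re-ordering.
#'
#' @param strains named list of [strain_params()], one per lineage; defaults
#'   to [default_strains()].
#' @param regimes character vector of regime kinds.
#' @param replicates replicates per lineage x regime cell.
#' @param n_cycles number of serial-passage cycles (0 gives an empty
#'   experiment with a zero-generation ledger).
#' @param seed integer top-level seed.
#' @param first_start_temp temperature of every population's first cycle.
#' @param inoculum_od OD830 seeding the first cycle.
#' @param ... passed to [simulate_cycle()].
#' @return a list of class `evolution_experiment` with `populations` (a named
#'   list; each population holds its trajectories plus metadata), `design`
#'   (one row per population) and `ledger` (the generation ledger from
#'   [count_generations()], aggregated over cycles).
#' @export
simulate_experiment <- function(strains = default_strains(),
                                regimes = c("slow", "fast", "random"),
                                replicates = 4, n_cycles = 3, seed = 1,
                                first_start_temp = 43, inoculum_od = 0.0025,
                                ...) {
  stopifnot(length(strains) >= 1, replicates >= 1, n_cycles >= 0)
  if (is.null(names(strains)))
    names(strains) <- vapply(strains, `[[`, "", "strain_id")
  design <- expand.grid(lineage = names(strains), regime = regimes,
                        replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$culture_id <- sprintf("%s%s-%d", toupper(substr(design$regime, 1, 1)),
                               design$lineage, design$replicate)
  populations <- list()
  ledgers <- list()
  for (i in seq_len(nrow(design))) {
    id <- design$culture_id[i]
    reg <- temperature_regime(design$regime[i])
    strain <- strains[[design$lineage[i]]]
    pop_seed <- derive_seed(seed, id)
    trajs <- list()
    start_temp <- first_start_temp
    od <- inoculum_od
    cyc <- 0L
    with_seed(pop_seed, {
      while (cyc < n_cycles) {
        cyc <- cyc + 1L
        tr <- simulate_cycle(strain, reg, start_temp, inoculum_od = od,
                             culture_id = id, cycle = cyc,
                             start_time_min = if (cyc == 1L) 0 else
                               trajs[[cyc - 1L]]$segments$t_end[
                                 nrow(trajs[[cyc - 1L]]$segments)],
                             ...)
        trajs[[cyc]] <- tr
        start_temp <- tr$end_temp
        od <- tr$end_od / tr$dilution_factor
      }
    })
    populations[[id]] <- list(culture_id = id, lineage = design$lineage[i],
                              regime = design$regime[i],
                              replicate = design$replicate[i],
                              trajectories = trajs)
    ledgers[[id]] <- if (n_cycles > 0)
      do.call(rbind, lapply(trajs, count_generations))
    else empty_ledger(id)
  }
  structure(list(populations = populations, design = design,
                 ledger = do.call(rbind, ledgers)),
            class = "evolution_experiment")
}

empty_ledger <- function(culture_id) {
  data.frame(culture_id = character(), cycle = integer(), segment = integer(),
             temperature_C = numeric(), od_start = numeric(),
             od_end = numeric(), generations = numeric())
}

#' Count generations along a simulated trajectory
#'
#' Within each temperature segment the number of doublings is
#' `g = log2(od_end / od_start)`, clipped below at zero; the noiseless
#' segment-boundary densities recorded by the simulator are used. Per-cycle
#' totals are additive over segments. Because a transferred culture regrows
#' to its pre-dilution density, a completed cycle also corresponds to
#' `log2(dilution_factor)` dilution-based generations; both accountings are
#' reported by [ledger_totals()] since neither is canonical.
#'
#' @param trajectory an `od_trajectory` from [simulate_cycle()].
#' @return data frame with one row per segment: `culture_id`, `cycle`,
#'   `segment`, `temperature_C`, `od_start`, `od_end`, `generations`.
#' @export
count_generations <- function(trajectory) {
  stopifnot(inherits(trajectory, "od_trajectory"))
  s <- trajectory$segments
  if (any(s$od_start <= 0) || any(s$od_end <= 0))
    stop_config("segment ODs must be positive")
  data.frame(culture_id = trajectory$culture_id, cycle = trajectory$cycle,
             segment = s$segment, temperature_C = s$temperature_C,
             od_start = s$od_start, od_end = s$od_end,
             generations = pmax(log2(s$od_end / s$od_start), 0))
}

#' Aggregate a generation ledger per population and temperature
#'
#' @param ledger output of [count_generations()] (rows may span cycles).
#' @param dilution_factor dilution per transfer, used for the dilution-based
#'   generation count.
#' @return list with `per_temperature` (culture x temperature doubling
#'   totals) and `per_cycle` (OD-based and dilution-based totals per cycle).
#' @export
ledger_totals <- function(ledger, dilution_factor = 201) {
  if (nrow(ledger) == 0) {
    return(list(
      per_temperature = data.frame(culture_id = character(),
                                   temperature_C = numeric(),
                                   generations = numeric()),
      per_cycle = data.frame(culture_id = character(), cycle = integer(),
                             generations_od = numeric(),
                             generations_dilution = numeric())))
  }
  per_temp <- stats::aggregate(generations ~ culture_id + temperature_C,
                               data = ledger, FUN = sum)
  per_cycle <- stats::aggregate(generations ~ culture_id + cycle,
                                data = ledger, FUN = sum)
  names(per_cycle)[3] <- "generations_od"
  per_cycle$generations_dilution <- log2(dilution_factor)
  list(per_temperature = per_temp, per_cycle = per_cycle)
}

#' Default strain parameters for the two founder lineages
#'
#' Realistic M9-glucose growth parameters for the two media-adapted founder
#' populations: fast growth near the optimum, slightly impaired growth at
#' 43 degrees and an order-of-magnitude slower growth at 15 degrees, with the
#' 606 founder marginally better at 15 degrees than the 607 founder. The
#' carrying capacity is set so the slow regime's 0.25 threshold sits at
#' roughly half of it.
#'
#' @param od_noise_sd measurement noise passed to both strains.
#' @return named list of two [strain_params()] objects (`"606"`, `"607"`).
#' @export
default_strains <- function(od_noise_sd = 0.002) {
  caps <- c("15" = 0.55, "37" = 0.55, "43" = 0.55)
  lags <- c("15" = 400, "37" = 120, "43" = 150)
  list(
    "606" = strain_params("606",
      mu_max = c("15" = 0.0016, "37" = 0.012, "43" = 0.010),
      lag = lags, capacity = caps, od_noise_sd = od_noise_sd),
    "607" = strain_params("607",
      mu_max = c("15" = 0.0014, "37" = 0.012, "43" = 0.010),
      lag = lags, capacity = caps, od_noise_sd = od_noise_sd))
}

#' Flatten an experiment's trajectories into one tidy table
#'
#' @param experiment an `evolution_experiment`.
#' @return data frame with columns `culture_id`, `cycle`, `time_min`,
#'   `od830`, `temperature_C`, `event` (`""`, `"switch"` or `"transfer"` at
#'   the first sample after the event).
#' @export
experiment_samples <- function(experiment) {
  rows <- lapply(experiment$populations, function(pop) {
    lapply(pop$trajectories, function(tr) {
      df <- tr$samples
      df$culture_id <- tr$culture_id
      df$cycle <- tr$cycle
      df$event <- ""
      for (j in seq_len(nrow(tr$events))) {
        at <- which(df$time_min >= tr$events$time_min[j])[1]
        if (!is.na(at)) df$event[at] <- tr$events$kind[j]
      }
      df[, c("culture_id", "cycle", "time_min", "od830", "temperature_C",
             "event")]
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}
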