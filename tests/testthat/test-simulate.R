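test_that("periodic cycles produce the scheduled switch events at exact thresholds", {
  strains <- default_strains()
  for (lineage in names(strains)) {
    for (start in c(15, 43)) {
      fast <- simulate_cycle(strains[[lineage]], temperature_regime("fast"),
                             start, seed = 42)
      sw <- fast$events[fast$events$kind == "switch", ]
      expect_equal(nrow(sw), 3)
      expect_equal(sw$od830, c(0.15, 0.30, 0.45), tolerance = 1e-9)
      expect_equal(sw$temp_from[1], start)
      expect_equal(sw$temp_to, vapply(sw$temp_from,
                                      function(x) if (x == 15) 43 else 15, 0))
      slow <- simulate_cycle(strains[[lineage]], temperature_regime("slow"),
                             start, seed = 42)
      expect_equal(sum(slow$events$kind == "switch"), 1)
      expect_equal(slow$events$od830[slow$events$kind == "switch"], 0.25,
                   tolerance = 1e-9)
    }
  }
})

test_that("switch counts hold across randomized strain parameters", {
  set.seed(99)
  for (i in 1:20) {
    st <- strain_params(
      "rnd",
      mu_max = c("15" = runif(1, 0.001, 0.003), "43" = runif(1, 0.006, 0.015)),
      lag = c("15" = runif(1, 0, 500), "43" = runif(1, 0, 300)),
      capacity = c("15" = runif(1, 0.5, 0.9), "43" = runif(1, 0.5, 0.9)),
      od_noise_sd = runif(1, 0, 0.004))
    expect_equal(sum(simulate_cycle(st, temperature_regime("fast"),
                                    sample(c(15, 43), 1),
                                    seed = i)$events$kind == "switch"), 3)
    expect_equal(sum(simulate_cycle(st, temperature_regime("slow"),
                                    sample(c(15, 43), 1),
                                    seed = i)$events$kind == "switch"), 1)
  }
})

test_that("random-regime segment durations are uniform within the printed bounds", {
  st <- default_strains()[["606"]]
  reg <- temperature_regime("random")
  dur <- list("15" = numeric(), "43" = numeric())
  seed <- 0
  while (length(dur[["15"]]) < 800 || length(dur[["43"]]) < 800) {
    seed <- seed + 1
    tr <- simulate_cycle(st, reg, if (seed %% 2) 43 else 15, seed = seed)
    s <- tr$segments
    # the last segment ends on the transfer trigger, not the drawn duration
    s <- s[-nrow(s), , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      tm <- as.character(s$temperature_C[i])
      dur[[tm]] <- c(dur[[tm]], s$t_end[i] - s$t_start[i])
    }
  }
  expect_true(all(dur[["43"]] >= 180 & dur[["43"]] <= 300))
  expect_true(all(dur[["15"]] >= 300 & dur[["15"]] <= 900))
  expect_gt(stats::ks.test(dur[["43"]], "punif", 180, 300)$p.value, 0.01)
  expect_gt(stats::ks.test(dur[["15"]], "punif", 300, 900)$p.value, 0.01)
})

test_that("trajectories are sampled on a strict 4-minute grid with positive OD", {
  tr <- simulate_cycle(default_strains()[["607"]], temperature_regime("fast"),
                       15, seed = 5)
  expect_true(all(diff(tr$samples$time_min) == 4))
  expect_true(all(tr$samples$od830 > 0))
  expect_true(all(tr$samples$temperature_C %in% c(15, 43)))
  # continuity: noiseless OD never jumps at a switch
  expect_true(all(abs(diff(tr$samples$od830_true)) < 0.05))
})

test_that("configuration errors are caught", {
  st <- default_strains()[["606"]]
  low_cap <- strain_params("x", mu_max = c("15" = 0.002, "43" = 0.01),
                           lag = c("15" = 100, "43" = 100),
                           capacity = c("15" = 0.3, "43" = 0.3))
  expect_error(simulate_cycle(low_cap, temperature_regime("fast"), 15),
               "threshold")
  expect_error(simulate_cycle(st, temperature_regime("slow"), 15,
                              inoculum_od = 0), "positive")
  expect_error(simulate_cycle(st, temperature_regime("slow"), 37), "15 or 43")
  expect_error(temperature_regime("fast", switch_ods = c(0.3, 0.2)),
               "increasing")
  expect_error(temperature_regime("random",
                                  random_durations = list("43" = c(5, 3),
                                                          "15" = c(5, 15))),
               "lower < upper")
})

test_that("the default experiment design yields 24 populations and alternates start temperatures", {
  ex <- simulate_experiment(n_cycles = 2, seed = 3)
  expect_length(ex$populations, 24)
  expect_equal(nrow(ex$design), 24)
  for (pop in ex$populations[c("S606-1", "F607-2")]) {
    trs <- pop$trajectories
    expect_equal(trs[[2]]$start_temp, trs[[1]]$end_temp)
    expect_equal(trs[[2]]$start_od, trs[[1]]$end_od / 201, tolerance = 1e-12)
  }
})

test_that("an empty design gives no trajectories and a zero-generation ledger", {
  ex <- simulate_experiment(strains = default_strains()[1],
                            regimes = "slow", replicates = 1, n_cycles = 0,
                            seed = 1)
  expect_length(ex$populations[[1]]$trajectories, 0)
  expect_equal(nrow(ex$ledger), 0)
  expect_equal(sum(ledger_totals(ex$ledger)$per_temperature$generations), 0)
})

test_that("the experiment is deterministic under a fixed seed", {
  a <- simulate_experiment(n_cycles = 1, seed = 11, replicates = 1)
  b <- simulate_experiment(n_cycles = 1, seed = 11, replicates = 1)
  expect_identical(experiment_samples(a), experiment_samples(b))
  expect_identical(a$ledger, b$ledger)
})

test_that("generation counting matches direct doubling arithmetic and is additive", {
  tr <- simulate_cycle(default_strains()[["606"]], temperature_regime("slow"),
                       43, inoculum_od = 0.0025, seed = 2)
  g <- count_generations(tr)
  # first segment: 0.0025 -> 0.25 is log2(100) doublings
  expect_equal(g$generations[1], log2(100), tolerance = 1e-9)
  # additivity: total equals the end-to-end doubling count
  expect_equal(sum(g$generations), log2(tr$end_od / tr$start_od),
               tolerance = 1e-9)
  # a full regrowth after a 100 uL -> 20.1 mL transfer is log2(201) doublings
  expect_equal(log2(201), 7.651052, tolerance = 1e-6)
  tot <- ledger_totals(g)
  expect_equal(tot$per_cycle$generations_dilution, log2(201))
  # flat segment contributes zero
  flat <- tr
  flat$segments$od_end[1] <- flat$segments$od_start[1]
  expect_equal(count_generations(flat)$generations[1], 0)
  bad <- tr; bad$segments$od_start[1] <- 0
  expect_error(count_generations(bad), "positive")
})

test_that("transmittance conversion is exact, strictly decreasing and invertible", {
  expect_equal(transmittance_to_od(1), 0)
  expect_equal(transmittance_to_od(0.1), 1)
  expect_equal(transmittance_to_od(0.95), 0.02227639, tolerance = 1e-6)
  tvals <- seq(0.05, 1, length.out = 50)
  od <- transmittance_to_od(tvals)
  expect_true(all(diff(od) < 0))
  expect_equal(10^(-od), tvals, tolerance = 1e-12)
  expect_error(transmittance_to_od(0), "0, 1")
  expect_error(transmittance_to_od(1.01), "0, 1")
})

test_that("carryover reproduces the internalized-fluctuation pattern", {
  st <- strain_params("int",
                      mu_max = c("15" = 0.0016, "43" = 0.010),
                      lag = c("15" = 0, "43" = 0),
                      capacity = c("15" = 0.55, "43" = 0.55),
                      od_noise_sd = 0,
                      carryover = list(temp = 15, prev = 15, factor = 0.6))
  reg <- temperature_regime("slow")
  # cycle starting at 15 after a 15 C segment: impaired cold growth
  after_cold <- simulate_cycle(st, reg, 15, prev_temp = 15, seed = 1)
  after_hot <- simulate_cycle(st, reg, 15, prev_temp = 43, seed = 1)
  t15 <- function(tr) {
    s <- tr$segments[tr$segments$temperature_C == 15, ][1, ]
    s$t_end - s$t_start
  }
  expect_gt(t15(after_cold), t15(after_hot)) # slower growth takes longer
})
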