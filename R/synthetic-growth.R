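#' Simulate one single-temperature growth-characterization curve
#'
#' The growth-rate assay grows an acclimated culture at one fixed temperature
#' and records OD on the instrument's 4-minute grid; this generator produces
#' such a curve from the modified Gompertz law with additive Gaussian
#' measurement noise.
#'
#' @param mu maximum specific growth rate (min^-1).
#' @param lag lag time (min).
#' @param capacity asymptotic OD830.
#' @param od0 inoculation density.
#' @param duration_min curve length (min).
#' @param dt_min sampling interval.
#' @param noise_sd additive OD noise.
#' @param noise_floor lower truncation of noisy OD.
#' @param seed optional seed (`NULL` = current stream).
#' @return data frame `time_min`, `od830`, `od830_true`.
#' @export
simulate_growth_curve <- function(mu, lag, capacity, od0 = 0.0025,
                                  duration_min = 2500, dt_min = 4,
                                  noise_sd = 0.002, noise_floor = 1e-4,
                                  seed = NULL) {
  stopifnot(mu > 0, capacity > od0, od0 > 0)
  gen <- function() {
    t <- seq(0, duration_min, by = dt_min)
    od_true <- gompertz_od(t, od0, log(capacity / od0), mu, lag)
    data.frame(time_min = t,
               od830 = pmax(od_true + stats::rnorm(length(t), 0, noise_sd),
                            noise_floor),
               od830_true = od_true)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Planted growth effects for the default synthetic assay
#'
#' Assigns each evolved population a ground-truth multiplicative change of
#' its ancestor's growth rate at 15 and 43 C, chosen so periodic-regime
#' strains are mostly generalists (rate gains at both temperatures) while
#' random-regime strains are mostly single-temperature specialists --
#' the contrast the strategy analysis is designed to detect.
#'
#' @param design data frame with `culture_id`, `lineage`, `regime`,
#'   `replicate` (as produced by [simulate_experiment()]).
#' @return data frame `strain_id`, `lineage`, `regime`, `mult_15`, `mult_43`.
#' @export
default_growth_effects <- function(design) {
  eff <- data.frame(strain_id = design$culture_id, lineage = design$lineage,
                    regime = design$regime, mult_15 = 1, mult_43 = 1)
  periodic <- eff$regime %in% c("slow", "fast")
  # periodic: 3 of 4 replicates generalists, one 43 C specialist
  gen <- periodic & design$replicate <= 3
  eff$mult_15[gen] <- 1.25
  eff$mult_43[gen] <- 1.35
  eff$mult_43[periodic & design$replicate == 4] <- 1.30
  # random: two 43 C specialists, one 15 C specialist, one not significant
  rnd <- eff$regime == "random"
  eff$mult_43[rnd & design$replicate <= 2] <- 1.35
  eff$mult_15[rnd & design$replicate == 3] <- 1.25
  eff
}

#' Generate a replicated growth-characterization assay
#'
#' Produces replicate growth curves for every evolved strain and its ancestor
#' at both stress temperatures. Evolved growth rates are the ancestor's
#' scaled by the planted multipliers with a small between-replicate
#' biological scatter.
#'
#' @param effects planted effects table from [default_growth_effects()].
#' @param strains ancestor [strain_params()] per lineage.
#' @param replicates curves per strain x temperature.
#' @param rep_cv between-replicate coefficient of variation of the true rate.
#' @param seed integer seed.
#' @param ... passed to [simulate_growth_curve()].
#' @return list with `curves` (named list of curve data frames) and `meta`
#'   (`curve_id`, `strain_id`, `lineage`, `role`, `temperature_C`,
#'   `replicate`, `true_mu`).
#' @export
generate_growth_assay <- function(effects, strains = default_strains(),
                                  replicates = 3, rep_cv = 0.03, seed = 1,
                                  ...) {
  rows <- list(); curves <- list()
  units <- rbind(
    data.frame(strain_id = effects$strain_id, lineage = effects$lineage,
               role = "evolved", mult_15 = effects$mult_15,
               mult_43 = effects$mult_43),
    data.frame(strain_id = paste0(names(strains), "P"),
               lineage = names(strains), role = "ancestor",
               mult_15 = 1, mult_43 = 1))
  with_seed(seed, {
    for (i in seq_len(nrow(units))) {
      anc <- strains[[units$lineage[i]]]
      for (temp in c(15, 43)) {
        tm <- as.character(temp)
        mu0 <- anc$mu_max[[tm]] * units[[paste0("mult_", tm)]][i]
        for (r in seq_len(replicates)) {
          mu <- mu0 * exp(stats::rnorm(1, 0, rep_cv))
          id <- sprintf("%s_T%d_r%d", units$strain_id[i], temp, r)
          curves[[id]] <- simulate_growth_curve(
            mu, anc$lag[[tm]], anc$capacity[[tm]], ...)
          rows[[id]] <- data.frame(
            curve_id = id, strain_id = units$strain_id[i],
            lineage = units$lineage[i], role = units$role[i],
            temperature_C = temp, replicate = r, true_mu = mu)
        }
      }
    }
  })
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  list(curves = curves, meta = meta)
}

#' Strategy classification of a whole growth assay
#'
#' Estimates every curve's growth rate, runs the pooled-variance
#' relative-growth test of each evolved strain against its lineage ancestor
#' at each temperature (pooling the variance across all replicate groups
#' measured at that temperature), and classifies each strain as generalist,
#' specialist or not-significant. The default `"consensus"` estimator takes
#' the spline estimate and cross-fits the Gompertz model; when the two
#' disagree by more than 20 percent -- which flags the occasional spline
#' failure on very low signal-to-noise curves -- the parametric estimate is
#' used instead.
#'
#' @param assay output of [generate_growth_assay()], or any list with
#'   `curves` and `meta` in the same layout.
#' @param alpha significance level.
#' @param method `"consensus"`, `"spline"` or `"gompertz"`.
#' @param pool_scope `"temperature"` pools the variance across every strain
#'   group at the temperature (default); `"pair"` uses only the two compared
#'   groups.
#' @param ... passed to [estimate_growth_rate()].
#' @return list with `estimates` (per-curve mu), `results` (per strain x
#'   temperature relative-growth rows) and `strategies` (per-strain calls).
#' @export
assay_strategy_analysis <- function(assay, alpha = 0.05,
                                    method = c("consensus", "spline",
                                               "gompertz"),
                                    pool_scope = c("temperature", "pair"),
                                    ...) {
  pool_scope <- match.arg(pool_scope)
  method <- match.arg(method)
  est_one <- function(curve) {
    if (method == "gompertz") return(fit_gompertz(curve)$mu_max)
    s <- estimate_growth_rate(curve, ...)$mu_max
    if (method == "spline") return(s)
    g <- tryCatch(fit_gompertz(curve)$mu_max, error = function(e) NA_real_)
    if (is.finite(g) && g > 0 && abs(s - g) / g > 0.2) g else s
  }
  meta <- assay$meta
  meta$mu_hat <- vapply(meta$curve_id,
                        function(id) est_one(assay$curves[[id]]), 0)
  results <- list()
  for (temp in sort(unique(meta$temperature_C))) {
    sub <- meta[meta$temperature_C == temp, ]
    groups <- split(sub$mu_hat, sub$strain_id)
    anc_of <- function(lin) paste0(lin, "P")
    for (sid in unique(sub$strain_id[sub$role == "evolved"])) {
      lin <- sub$lineage[sub$strain_id == sid][1]
      pool <- if (pool_scope == "temperature") groups else
        groups[c(sid, anc_of(lin))]
      r <- relative_growth_test(groups[[sid]], groups[[anc_of(lin)]],
                                pool = pool, strain_id = sid,
                                temperature = temp)
      results[[paste(sid, temp)]] <- r
    }
  }
  res_df <- do.call(rbind, lapply(results, function(r)
    data.frame(strain_id = r$strain_id, temperature_C = r$temperature,
               ratio = r$ratio, t_stat = r$t_stat, df = r$df,
               p_value = r$p_value)))
  rownames(res_df) <- NULL
  strains <- unique(res_df$strain_id)
  strategies <- do.call(rbind, lapply(strains, function(sid) {
    call <- classify_strategy(results[[paste(sid, 15)]],
                              results[[paste(sid, 43)]], alpha = alpha)
    data.frame(strain_id = sid, category = call$category,
               ratio_15 = call$ratio_15, p_15 = call$p_15,
               ratio_43 = call$ratio_43, p_43 = call$p_43)
  }))
  list(estimates = meta, results = res_df, strategies = strategies)
}
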