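#' Configuration for the synthetic Biolog plate generator
#'
#' Describes a ground-truth phenotype-array experiment in the 92-dimensional
#' normalized feature space. Ancestor phenotypes sit at a base vector at the
#' 37 C optimum and are displaced along one orthonormal axis per stress
#' temperature (the ancestral plasticity the restoration analysis measures);
#' each evolved strain receives a planted restoration category at each stress
#' temperature, realized as a mean displacement along the relevant axis (the
#' stress axis for the five movement categories; a third, ancestor-neutral
#' axis for `novel`). Displacements are expressed in multiples of the
#' replicate noise standard deviation, mapped back to 96 raw wells (inverting
#' the plate normalization), and replicate plates get i.i.d. Gaussian well
#' noise.
#'
#' @param strains data frame of evolved strains (`strain_id`, `lineage`).
#' @param ancestors data frame of ancestor strains (`strain_id`, `lineage`).
#' @param planted data frame (`strain_id`, `temperature_C` in \{15, 43\},
#'   `category` from [restoration_categories]) with one row per evolved
#'   strain x stress temperature.
#' @param effect_size planted displacement magnitude in noise-SD units.
#' @param stress_sep named vector: ancestor displacement (noise-SD units)
#'   from the 37 C base at each stress temperature. The 43 C displacement is
#'   larger by default -- the hot condition is the more perturbed state.
#' @param novel_scale multiple of `effect_size` used for the `novel` axis
#'   displacement.
#' @param noise_sd replicate noise of the assay wells (OD590 units); this is
#'   dominated by biological variation between replicate inoculations.
#' @param control_noise_frac noise of the control and dye wells relative to
#'   `noise_sd`; control wells carry no growth signal and read far more
#'   stably than assay wells.
#' @param reps_evolved,reps_ancestor technical replicates per strain x
#'   temperature (3 evolved / 6 ancestor by default; >= 2 required).
#' @param layout plate layout.
#' @param axis_seed seed fixing the orthonormal structural axes.
#' @return object of class `synthetic_biolog_config`.
#' @export
synthetic_biolog_config <- function(strains, ancestors, planted,
                                    effect_size = 5,
                                    stress_sep = c("15" = 2.5, "43" = 3) * effect_size,
                                    novel_scale = 1.2,
                                    noise_sd = 0.02, control_noise_frac = 0.1,
                                    reps_evolved = 3, reps_ancestor = 6,
                                    layout = gen3_layout(),
                                    axis_seed = 20210722) {
  if (reps_evolved < 2 || reps_ancestor < 2)
    stop_config("replicate counts must be at least 2")
  if (effect_size < 0) stop_config("effect size must be non-negative")
  stopifnot(all(c("strain_id", "lineage") %in% names(strains)),
            all(c("strain_id", "lineage") %in% names(ancestors)),
            all(c("strain_id", "temperature_C", "category") %in% names(planted)))
  if (!all(planted$category %in% restoration_categories))
    stop_config("unknown planted categories")
  if (!all(planted$temperature_C %in% c(15, 43)))
    stop_config("planted temperatures must be 15 or 43")
  layout <- validate_layout(layout)
  # three fixed orthonormal axes in the 92-feature space
  axes <- with_seed(axis_seed, {
    qr.Q(qr(matrix(stats::rnorm(92 * 3), 92, 3)))
  })
  colnames(axes) <- c("stress15", "stress43", "novel")
  base <- with_seed(axis_seed + 1, stats::runif(92, 0.2, 0.8))
  names(base) <- feature_names(layout)
  noise <- rep(noise_sd, 96)
  noise[layout$role %in% c("negative_control", "positive_control", "dye")] <-
    noise_sd * control_noise_frac
  structure(list(strains = strains, ancestors = ancestors, planted = planted,
                 effect_size = effect_size, stress_sep = stress_sep,
                 novel_scale = novel_scale, noise_sd = noise_sd,
                 well_noise = noise,
                 reps_evolved = reps_evolved, reps_ancestor = reps_ancestor,
                 layout = layout, axes = axes, base = base),
            class = "synthetic_biolog_config")
}

#' Default synthetic Biolog design
#'
#' Mirrors the full study design: 24 evolved strains (2 lineages x 3 regimes
#' x 4 replicates) assayed in triplicate at 15, 37 and 43 C plus the two
#' ancestors in six technical replicates at each temperature -- 216 + 36 =
#' 252 plates. Six strains carry planted `novel` responses at both stress
#' temperatures; the remaining 18 cycle through the six other categories so
#' every category is planted several times.
#'
#' @param ... passed on to [synthetic_biolog_config()].
#' @return a `synthetic_biolog_config`.
#' @export
default_biolog_config <- function(...) {
  lineages <- c("606", "607"); regimes <- c("slow", "fast", "random")
  grid <- expand.grid(replicate = 1:4, regime = regimes, lineage = lineages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  strains <- data.frame(
    strain_id = sprintf("%s%s-%d", toupper(substr(grid$regime, 1, 1)),
                        grid$lineage, grid$replicate),
    lineage = grid$lineage)
  ancestors <- data.frame(strain_id = c("606P", "607P"),
                          lineage = lineages)
  novel_ids <- strains$strain_id[seq(1, 24, by = 4)] # 6 strains
  others <- setdiff(strains$strain_id, novel_ids)
  cats <- setdiff(restoration_categories, "novel") # 6 categories
  # novel displacements alternate in sign across strains so the novel axis
  # stays uncorrelated with the stress axes in the sample covariance
  planted <- rbind(
    data.frame(strain_id = rep(novel_ids, each = 2),
               temperature_C = rep(c(15, 43), 6),
               category = "novel",
               novel_sign = rep(c(1, -1), each = 2, length.out = 12)),
    data.frame(strain_id = rep(others, each = 2),
               temperature_C = rep(c(15, 43), 18),
               category = cats[(seq_len(36) - 1) %% 6 + 1],
               novel_sign = 1))
  synthetic_biolog_config(strains, ancestors, planted, ...)
}

# Mean feature vector of a (strain, temperature) condition under the config.
target_features <- function(config, strain_id, temperature, role) {
  s <- config$noise_sd
  a_o <- config$base
  if (temperature == 37) stress_axis <- NULL
  else stress_axis <- config$axes[, paste0("stress", temperature)]
  a_s <- if (temperature == 37) a_o else
    a_o + config$stress_sep[[as.character(temperature)]] * s * stress_axis
  if (role == "ancestor" || temperature == 37) {
    return(if (role == "ancestor") a_s else a_o)
  }
  pl <- config$planted
  row <- pl[pl$strain_id == strain_id & pl$temperature_C == temperature, ]
  if (nrow(row) != 1)
    stop_config("no planted category for %s at %g C", strain_id, temperature)
  d <- a_s - a_o
  sgn <- if ("novel_sign" %in% names(row)) row$novel_sign else 1
  switch(row$category,
         unrestored = a_s,
         uninformative = a_s,
         restored = a_o,
         partially_restored = (a_s + a_o) / 2,
         over_restored = a_o - 0.5 * d,
         reinforced = a_s + 0.5 * d,
         novel = a_s + sgn * config$novel_scale * config$effect_size * s *
           config$axes[, "novel"])
}

# Invert normalize_plate(): build 96 raw wells whose normalized features
# equal `f` exactly (before noise).
features_to_wells <- function(f, layout, nc_val = 0.05, pc_val = 1.2,
                              dye_val = 1.6) {
  od <- numeric(96)
  met <- layout$well[layout$role == "metabolic"]
  chem <- layout$well[layout$role == "chemical"]
  od[layout$well[layout$role == "negative_control"]] <- nc_val
  od[layout$well[layout$role == "positive_control"]] <- pc_val
  od[layout$well[layout$role == "dye"]] <- dye_val
  od[met] <- nc_val + f[seq_along(met)]
  od[chem] <- pc_val - f[length(met) + seq_along(chem)]
  od
}

#' Generate a synthetic Biolog plate set with known ground truth
#'
#' Emits raw 96-well plates for every strain x temperature x replicate of the
#' configured design, with planted restoration displacements applied in the
#' 92-feature space and mapped back to wells, plus i.i.d. Gaussian well
#' noise.
#'
#' @param config a [synthetic_biolog_config()].
#' @param seed integer seed.
#' @return object of class `biolog_plates`: list with `od` (plates x 96
#'   matrix), `meta` (`plate_id`, `strain_id`, `lineage`, `temperature_C`,
#'   `replicate`, `role`), `layout`, and `truth` (the config, for
#'   recovery evaluation).
#' @export
generate_biolog_plates <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_biolog_config"))
  temps <- c(15, 37, 43)
  sets <- rbind(
    data.frame(strain_id = rep(config$strains$strain_id, each = 3),
               lineage = rep(config$strains$lineage, each = 3),
               temperature_C = rep(temps, nrow(config$strains)),
               role = "evolved", reps = config$reps_evolved),
    data.frame(strain_id = rep(config$ancestors$strain_id, each = 3),
               lineage = rep(config$ancestors$lineage, each = 3),
               temperature_C = rep(temps, nrow(config$ancestors)),
               role = "ancestor", reps = config$reps_ancestor))
  n <- sum(sets$reps)
  od <- matrix(NA_real_, n, 96)
  meta <- data.frame(plate_id = character(n), strain_id = character(n),
                     lineage = character(n), temperature_C = numeric(n),
                     replicate = integer(n), role = character(n))
  with_seed(seed, {
    at <- 0L
    for (i in seq_len(nrow(sets))) {
      f <- target_features(config, sets$strain_id[i], sets$temperature_C[i],
                           sets$role[i])
      clean <- features_to_wells(f, config$layout)
      for (r in seq_len(sets$reps[i])) {
        at <- at + 1L
        od[at, ] <- clean + stats::rnorm(96, 0, config$well_noise)
        meta[at, ] <- list(
          sprintf("%s_T%g_r%d", sets$strain_id[i], sets$temperature_C[i], r),
          sets$strain_id[i], sets$lineage[i], sets$temperature_C[i], r,
          sets$role[i])
      }
    }
  })
  rownames(od) <- meta$plate_id
  structure(list(od = od, meta = meta, layout = config$layout,
                 truth = config),
            class = "biolog_plates")
}

#' @export
print.biolog_plates <- function(x, ...) {
  cat(sprintf("<biolog_plates> %d plates (%d evolved, %d ancestor) at temperatures %s\n",
              nrow(x$od), sum(x$meta$role == "evolved"),
              sum(x$meta$role == "ancestor"),
              paste(sort(unique(x$meta$temperature_C)), collapse = "/")))
  invisible(x)
}

#' Evaluate recovery of planted restoration categories
#'
#' Runs the full analysis pipeline on a synthetic plate set -- normalization,
#' centering, PCA, ancestor centroids and per-component restoration calls --
#' and compares, for every planted (strain, stress temperature) pair, the
#' call on the principal component most aligned with the planted displacement
#' axis (the stress axis for movement categories, the ancestor-neutral axis
#' for `novel`/`uninformative`) against the planted truth.
#'
#' @param plates output of [generate_biolog_plates()].
#' @param n_components components to retain (the structural design has 3
#'   axes).
#' @param alpha,fwer,by passed to [classify_restoration()].
#' @return data frame (`strain_id`, `temperature_C`, `planted`, `component`,
#'   `called`, `recovered`).
#' @export
recover_planted_restoration <- function(plates, n_components = 3,
                                        alpha = 0.05, fwer = "holm",
                                        by = "lineage") {
  config <- plates$truth
  feats <- normalize_plates(plates, plates$layout)
  centered <- assemble_and_center(feats)
  model <- fit_pca(centered, n_components = n_components)
  calls <- classify_restoration(model, plates$meta, alpha = alpha,
                                fwer = fwer, by = by)
  k <- model$retained
  align <- function(axis) {
    proj <- abs(drop(crossprod(model$loadings[, seq_len(k), drop = FALSE],
                               axis)))
    unname(which.max(proj))
  }
  comp_for <- c("15" = align(config$axes[, "stress15"]),
                "43" = align(config$axes[, "stress43"]),
                novel = align(config$axes[, "novel"]))
  pl <- config$planted
  pl$component <- ifelse(pl$category %in% c("novel", "uninformative"),
                         comp_for[["novel"]],
                         comp_for[as.character(pl$temperature_C)])
  idx <- match(paste(pl$strain_id, pl$temperature_C, pl$component),
               paste(calls$strain_id, calls$temperature_C, calls$component))
  pl$called <- calls$category[idx]
  pl$recovered <- pl$called == pl$category
  names(pl)[names(pl) == "category"] <- "planted"
  pl
}
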