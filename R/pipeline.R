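#' Default pipeline configuration
#'
#' @param out_dir output directory for stage tables and the report.
#' @param seed top-level seed, fanned out per stage via [derive_seed()].
#' @param alpha significance level used by every stage.
#' @param n_cycles serial-passage cycles to simulate.
#' @param replicates populations per lineage x regime.
#' @param stages named logical vector toggling stages.
#' @return config list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir = "results", seed = 1, alpha = 0.05,
                            n_cycles = 2, replicates = 4,
                            stages = c(simulate = TRUE, growth = TRUE,
                                       mutations = TRUE, biolog = TRUE)) {
  list(out_dir = out_dir, seed = seed, alpha = alpha,
       design = list(lineages = c("606", "607"),
                     regimes = c("slow", "fast", "random"),
                     replicates = replicates, n_cycles = n_cycles),
       stages = as.list(stages))
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; missing fields are filled from
#'   [pipeline_config()] defaults.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- pipeline_config()
  out <- utils::modifyList(base, cfg)
  if (!is.numeric(out$seed) || out$seed != round(out$seed))
    stop_config("seed must be an integer")
  if (out$alpha <= 0 || out$alpha >= 1) stop_config("alpha must be in (0, 1)")
  out
}

# Deterministic content hash (polynomial rolling hash over the serialized
# object) used for report provenance; no cryptographic strength intended.
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order -- simulate (fluctuation-regime
#' trajectories and the generation ledger), growth (spline rate estimates,
#' relative-growth tests, strategy calls, variance and enrichment tests),
#' mutations (incidence matrix, per-generation rates, gene enrichment, class
#' comparisons) and biolog (plate processing, PCA, restoration calls, group
#' tests) -- writing each stage's tables under `out_dir` and a consolidated
#' JSON + text report. Stages can be toggled off; stages whose inputs were
#' disabled degrade gracefully and record a warning (e.g. strategy-grouped
#' tests are skipped when the growth stage is off). Every statistical
#' decision (test, sidedness, correction, alpha) is echoed into the report so
#' the output is self-documenting.
#'
#' @param config list from [pipeline_config()] or [read_pipeline_config()].
#' @return the run report (list), invisibly written to
#'   `out_dir/report.json` and `out_dir/report.txt`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config$out_dir, "INCOMPLETE")
  file.create(marker)
  report <- list(config_hash = content_hash(config), seed = config$seed,
                 alpha = config$alpha,
                 package_version = as.character(utils::packageVersion("fluctevo")),
                 warnings = character(), decisions = character(),
                 stages = list())
  on <- function(stage) isTRUE(config$stages[[stage]])
  note <- function(...) report$decisions <<- c(report$decisions, sprintf(...))
  warn <- function(...) report$warnings <<- c(report$warnings, sprintf(...))
  fail <- function(stage, e) stop_config("stage '%s' failed: %s",
                                         stage, conditionMessage(e))

  strategies <- NULL
  experiment <- NULL

  if (on("simulate")) tryCatch({
    experiment <- simulate_experiment(
      regimes = config$design$regimes,
      replicates = config$design$replicates,
      n_cycles = config$design$n_cycles,
      seed = derive_seed(config$seed, "simulate"))
    write_tsv(experiment_samples(experiment),
              file.path(config$out_dir, "trajectories.tsv"))
    write_tsv(experiment$ledger, file.path(config$out_dir, "ledger.tsv"))
    totals <- ledger_totals(experiment$ledger)
    write_tsv(totals$per_temperature,
              file.path(config$out_dir, "generations_per_temperature.tsv"))
    report$stages$simulate <- list(
      n_populations = length(experiment$populations),
      n_cycles = config$design$n_cycles,
      total_generations = sum(experiment$ledger$generations))
    note("simulate: OD thresholds slow=0.25, fast=0.15/0.30/0.45; random durations U(3,5)h at 43C, U(5,15)h at 15C; transfer at 95%% of capacity; dilution 1:201")
  }, error = function(e) fail("simulate", e))

  if (on("growth")) tryCatch({
    design <- if (!is.null(experiment)) experiment$design else
      simulate_experiment(replicates = config$design$replicates,
                          n_cycles = 0, seed = 1)$design
    assay <- generate_growth_assay(default_growth_effects(design),
                                   seed = derive_seed(config$seed, "growth"))
    ana <- assay_strategy_analysis(assay, alpha = config$alpha)
    strategies <- ana$strategies
    write_tsv(ana$results, file.path(config$out_dir, "relative_growth.tsv"))
    write_tsv(strategies, file.path(config$out_dir, "strategy_calls.tsv"))
    regime <- design$regime[match(strategies$strain_id, design$culture_id)]
    periodic <- regime %in% c("slow", "fast")
    gen <- strategies$category == "generalist"
    fisher_p <- fisher_strategy_enrichment(matrix(
      c(sum(gen & periodic), sum(!gen & periodic),
        sum(gen & !periodic), sum(!gen & !periodic)), 2))
    vr <- lapply(c(15, 43), function(tm) {
      r <- ana$results[ana$results$temperature_C == tm, ]
      p_idx <- periodic[match(r$strain_id, strategies$strain_id)]
      variance_ratio_test(r$ratio[p_idx], r$ratio[!p_idx])
    })
    report$stages$growth <- list(
      n_strategy_calls = nrow(strategies),
      categories = as.list(table(strategies$category)),
      generalist_enrichment_fisher_p = fisher_p,
      variance_ratio_15 = vr[[1]], variance_ratio_43 = vr[[2]])
    note("growth: spline mu_max on log OD (GCV, spar floor 0.3), window 2500 min; two-sided pooled t (variance pooled across all strain groups per temperature); strategy alpha=%g; Fisher exact two-sided for generalist enrichment; two-sided F-test for variance", config$alpha)
  }, error = function(e) fail("growth", e))

  if (on("mutations")) tryCatch({
    mc <- default_mutation_config()
    records <- generate_mutation_table(mc, seed = derive_seed(config$seed, "mutations"))
    records <- filter_by_frequency(records, 0.05)
    strain_ids <- unlist(mc$groups, use.names = FALSE)
    strain_meta <- data.frame(
      strain_id = strain_ids,
      lineage = substr(strain_ids, 2, 4),
      regime = c(S = "slow", F = "fast", R = "random")[substr(strain_ids, 1, 1)])
    strain_meta$periodicity <- ifelse(strain_meta$regime == "random",
                                      "random", "periodic")
    im <- collapse_to_gene(records, strain_meta = strain_meta,
                           gene_universe = mc$genes$gene)
    enr_lineage <- z_enrichment(im, "lineage")
    enr_regime <- z_enrichment(im, "periodicity")
    write_tsv(data.frame(gene = rownames(im$incidence), im$incidence,
                         check.names = FALSE),
              file.path(config$out_dir, "incidence.tsv"))
    write_tsv(enr_lineage, file.path(config$out_dir, "enrichment_lineage.tsv"))
    write_tsv(enr_regime, file.path(config$out_dir, "enrichment_regime.tsv"))
    ld <- vapply(colnames(im$counts), function(s) sum(
      records$mutation_class == "large_deletion" & records$strain_id == s), 0)
    mw <- class_count_compare(ld[strain_meta$lineage == "606"],
                              ld[strain_meta$lineage == "607"],
                              alternative = "greater")
    report$stages$mutations <- list(
      n_records = nrow(records), n_genes_tested = nrow(enr_lineage),
      top_lineage_gene = enr_lineage$gene[1],
      top_lineage_q = enr_lineage$fdr_q[1],
      large_deletion_mw_p = mw$p_value)
    note("mutations: 5%% population-frequency filter; gene-level collapse with anchor genes; pooled two-proportion z (two-sided) for genes in >=3 strains with BH FDR; one-sided exact Mann-Whitney for class counts")
  }, error = function(e) fail("mutations", e))

  if (on("biolog")) tryCatch({
    bc <- default_biolog_config()
    plates <- generate_biolog_plates(bc, seed = derive_seed(config$seed, "biolog"))
    plates <- qc_impute(plates)
    feats <- normalize_plates(plates, plates$layout)
    centered <- assemble_and_center(feats)
    model <- fit_pca(centered, n_components = 3)
    calls <- classify_restoration(model, plates$meta, alpha = config$alpha)
    write_tsv(calls, file.path(config$out_dir, "restoration_calls.tsv"))
    write_tsv(attr(calls, "summary"),
              file.path(config$out_dir, "restoration_summary.tsv"))
    tests <- restoration_group_tests(calls)
    if (!is.null(strategies)) {
      grouping <- stats::setNames(
        ifelse(strategies$category == "generalist", "generalist", "other"),
        strategies$strain_id)
      tests <- rbind(tests,
                     restoration_group_tests(calls, grouping = grouping))
    } else {
      warn("growth stage disabled: strategy-grouped restoration tests skipped")
    }
    write_tsv(tests, file.path(config$out_dir, "restoration_tests.tsv"))
    cl <- cluster_samples(centered)
    writeLines(cl$newick, file.path(config$out_dir, "dendrogram.nwk"))
    report$stages$biolog <- list(
      n_plates = nrow(plates$od), n_features = ncol(feats),
      retained_components = model$retained,
      variance_explained = sum(model$prop_var[seq_len(model$retained)]),
      headline_categories = as.list(table(attr(calls, "summary")$headline)))
    note("biolog: plate normalization (well-NC, PC-well), wells 86/94 dropped, 92 features, column centering; PCA with 3 retained components; Welch t-tests with Holm FWER per strain x temperature; Ward/Euclidean clustering")
  }, error = function(e) fail("biolog", e))

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- c(sprintf("fluctevo pipeline report (seed %d, config %s)",
                   config$seed, report$config_hash),
           sprintf("stage %s: %s", names(report$stages),
                   vapply(report$stages, function(s)
                     paste(names(s), vapply(s, function(v)
                       paste(format(unlist(v)), collapse = "/"), ""),
                       sep = "=", collapse = "; "), "")),
           if (length(report$warnings)) paste("WARNING:", report$warnings),
           paste("DECISION:", report$decisions))
  writeLines(txt, file.path(config$out_dir, "report.txt"))
  unlink(marker)
  invisible(report)
}

#' Validate pipeline input tables against simple schemas
#'
#' Checks each file for readability, required columns, column types and
#' value ranges, and returns every violation instead of stopping at the
#' first.
#'
#' @param paths named character vector of TSV/CSV file paths.
#' @param schemas named list (same names) of schemas: each a list with
#'   `columns` (named character vector, column -> `"numeric"`/`"character"`)
#'   and optional `ranges` (named list, column -> `c(min, max)`).
#' @return data frame `file`, `check`, `detail` (zero rows when valid).
#' @export
validate_inputs <- function(paths, schemas) {
  issues <- list()
  add <- function(f, check, detail)
    issues[[length(issues) + 1L]] <<- data.frame(file = f, check = check,
                                                 detail = detail)
  for (nm in names(paths)) {
    path <- paths[[nm]]
    schema <- schemas[[nm]]
    if (is.null(schema)) { add(nm, "schema", "no schema supplied"); next }
    tab <- tryCatch({
      sep <- if (grepl("\\.csv$", path)) "," else "\t"
      suppressWarnings(
        utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE))
    }, error = function(e) e)
    if (inherits(tab, "error")) {
      add(nm, "unreadable", conditionMessage(tab)); next
    }
    for (col in names(schema$columns)) {
      if (!col %in% names(tab)) {
        add(nm, "missing_column", col)
        next
      }
      want <- schema$columns[[col]]
      if (want == "numeric" && !is.numeric(tab[[col]]))
        add(nm, "type", sprintf("%s is not numeric", col))
    }
    for (col in names(schema$ranges %||% list())) {
      if (!col %in% names(tab) || !is.numeric(tab[[col]])) next
      rng <- schema$ranges[[col]]
      bad <- sum(tab[[col]] < rng[1] | tab[[col]] > rng[2], na.rm = TRUE)
      if (bad > 0)
        add(nm, "range",
            sprintf("%d values of %s outside [%g, %g]", bad, col,
                    rng[1], rng[2]))
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(file = character(), check = character(), detail = character())
}
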