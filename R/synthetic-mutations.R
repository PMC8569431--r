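#' Configuration for the synthetic mutation-table generator
#'
#' Describes a ground-truth mutation process: per-group Bernoulli gene
#' mutation probabilities (groups are arbitrary strain sets, typically
#' lineage x regime cells), a distribution over mutation classes and a
#' population-frequency distribution with support on (0, 1]. The defaults of
#' [default_mutation_config()] emulate the structure of a 24-population
#' incidence matrix with a handful of strongly parallel genes.
#'
#' @param genes data frame with columns `gene` and optionally `anchor_gene`
#'   and `category`, or a character vector of gene names.
#' @param groups named list mapping group names to character vectors of
#'   strain ids (disjoint).
#' @param prob numeric matrix of Bernoulli probabilities, genes x groups
#'   (dimnames must match).
#' @param class_probs named probability vector over [mutation_classes]
#'   (sums to 1).
#' @param sample_kind `"population"` or `"clone"`.
#' @param freq_fn function(n) drawing n frequencies in (0, 1]; clone tables
#'   always use frequency 1.
#' @return object of class `synthetic_mutation_config`.
#' @export
synthetic_mutation_config <- function(genes, groups, prob,
                                      class_probs = default_class_probs(),
                                      sample_kind = "population",
                                      freq_fn = default_freq_fn) {
  if (is.character(genes)) genes <- data.frame(gene = genes)
  if (nrow(genes) == 0) stop_config("gene list must not be empty")
  if (!"category" %in% names(genes)) genes$category <- "other"
  prob <- as.matrix(prob)
  if (!identical(rownames(prob), genes$gene) ||
      !identical(colnames(prob), names(groups)))
    stop_config("prob must have genes as rownames and groups as colnames")
  if (any(prob < 0) || any(prob > 1))
    stop_config("mutation probabilities must lie in [0, 1]")
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop_config("class distribution must sum to 1")
  if (!all(names(class_probs) %in% mutation_classes))
    stop_config("class_probs has unknown classes")
  structure(list(genes = genes, groups = groups, prob = prob,
                 class_probs = class_probs, sample_kind = sample_kind,
                 freq_fn = freq_fn),
            class = "synthetic_mutation_config")
}

#' @rdname synthetic_mutation_config
#' @export
default_class_probs <- function() {
  c(nonsynonymous = 0.40, small_indel = 0.20, large_deletion = 0.08,
    amplification = 0.05, IS_insertion = 0.09, intergenic = 0.12,
    synonymous = 0.04, nonsense = 0.02)
}

#' @rdname synthetic_mutation_config
#' @param n number of frequencies to draw.
#' @export
default_freq_fn <- function(n) pmin(pmax(stats::rbeta(n, 2, 0.8), 0.01), 1)

#' Generate a synthetic mutation-call table with known ground truth
#'
#' Draws, for every strain of every group, an independent Bernoulli hit per
#' gene with the configured group-specific probability; hits receive a
#' mutation class from the configured class distribution and (for population
#' tables) a frequency from the configured spectrum. Planted group contrasts
#' (a gene with high probability in one group and zero in another) are
#' recoverable downstream by [z_enrichment()].
#'
#' @param config a [synthetic_mutation_config()].
#' @param seed integer seed.
#' @return mutation record data frame (`strain_id`, `sample_kind`, `gene`,
#'   `anchor_gene`, `mutation_class`, `frequency`, `position`) with an
#'   attribute `"truth"` holding the configured probability matrix.
#' @export
generate_mutation_table <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_mutation_config"))
  with_seed(seed, {
    rows <- list()
    for (grp in names(config$groups)) {
      for (strain in config$groups[[grp]]) {
        hit <- stats::runif(nrow(config$genes)) < config$prob[, grp]
        if (!any(hit)) next
        ng <- sum(hit)
        rows[[length(rows) + 1L]] <- data.frame(
          strain_id = strain,
          sample_kind = config$sample_kind,
          gene = config$genes$gene[hit],
          anchor_gene = if ("anchor_gene" %in% names(config$genes))
            config$genes$anchor_gene[hit] else config$genes$gene[hit],
          mutation_class = sample(names(config$class_probs), ng,
                                  replace = TRUE, prob = config$class_probs),
          frequency = if (config$sample_kind == "clone") rep(1, ng)
                      else config$freq_fn(ng),
          position = sample.int(4629812L, ng))
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(strain_id = character(), sample_kind = character(),
                 gene = character(), anchor_gene = character(),
                 mutation_class = character(), frequency = numeric(),
                 position = integer())
    rownames(out) <- NULL
    attr(out, "truth") <- config$prob
    out
  })
}

#' Default synthetic mutation design mirroring a 24-population experiment
#'
#' Two lineages x three regimes x four replicates, with background genes
#' mutated at a common low probability plus planted contrasts: one gene
#' strongly enriched in lineage B, one in the periodic regimes of lineage A,
#' and one in the random regime, echoing the kind of gene-level parallelism
#' such experiments report.
#'
#' @param background_p Bernoulli probability of each background gene.
#' @return a [synthetic_mutation_config()].
#' @export
default_mutation_config <- function(background_p = 0.15) {
  lineages <- c("606", "607"); regimes <- c("slow", "fast", "random")
  groups <- list()
  for (l in lineages) for (r in regimes)
    groups[[paste(l, r, sep = "_")]] <-
      sprintf("%s%s-%d", toupper(substr(r, 1, 1)), l, 1:4)
  genes <- data.frame(
    gene = c("rho", "lon", "nadR", "deaD", "rpsE", "groEL-ES", "cspA",
             "fabF", "mrdA", "thiC", paste0("bg", 1:10)),
    category = c("regulatory", "heat_shock", "metabolic", "cold_shock",
                 "regulatory", "heat_and_cold_shock", "cold_shock",
                 "cold_shock", "membrane_cell_wall", "metabolic",
                 rep("other", 10)))
  prob <- matrix(background_p, nrow(genes), length(groups),
                 dimnames = list(genes$gene, names(groups)))
  is607 <- grepl("^607", colnames(prob))
  periodic <- grepl("(slow|fast)$", colnames(prob))
  prob["rho", ] <- ifelse(is607, 0.9, 0)
  prob["nadR", ] <- ifelse(is607, 0.6, 0.1)
  prob["lon", ] <- ifelse(!is607 & periodic, 0.9, 0.3)
  prob["deaD", ] <- ifelse(!periodic, 0.6, 0.05)
  prob["rpsE", ] <- ifelse(periodic, 0.5, 0.05)
  prob["groEL-ES", ] <- ifelse(periodic, 0.3, 0)
  prob["mrdA", ] <- ifelse(!periodic, 0.5, 0.1)
  synthetic_mutation_config(genes, groups, prob)
}
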