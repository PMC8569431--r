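#' Closed set of mutation classes
#' @export
mutation_classes <- c("nonsynonymous", "synonymous", "small_indel",
                      "large_deletion", "amplification", "IS_insertion",
                      "intergenic", "nonsense")

#' Functional gene categories used for count comparisons
#' @export
gene_categories <- c("heat_shock", "cold_shock", "heat_and_cold_shock",
                     "regulatory", "membrane_cell_wall", "metabolic",
                     "transporter", "other")

validate_mutation_records <- function(records) {
  need <- c("strain_id", "sample_kind", "gene", "mutation_class", "frequency")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_config("mutation records need columns: %s", paste(need, collapse = ", "))
  if (nrow(records) > 0) {
    if (any(records$frequency <= 0) || any(records$frequency > 1))
      stop_config("frequencies must lie in (0, 1]")
    bad <- setdiff(unique(records$mutation_class), mutation_classes)
    if (length(bad))
      stop_config("unknown mutation classes: %s", paste(bad, collapse = ", "))
  }
  records
}

#' Drop low-frequency population mutation calls
#'
#' Population-sequencing calls below the frequency threshold (default 5
#' percent, with the boundary kept) are removed; clone calls are by
#' definition fixed and pass through untouched.
#'
#' @param records mutation record data frame (columns `strain_id`,
#'   `sample_kind`, `gene`, `mutation_class`, `frequency`, optionally
#'   `anchor_gene`, `position`).
#' @param min_frequency threshold in (0, 1].
#' @return filtered records.
#' @export
filter_by_frequency <- function(records, min_frequency = 0.05) {
  if (min_frequency <= 0 || min_frequency > 1)
    stop_config("min_frequency must lie in (0, 1]")
  records <- validate_mutation_records(records)
  if (nrow(records) == 0) return(records)
  keep <- records$sample_kind == "clone" | records$frequency >= min_frequency
  records[keep, , drop = FALSE]
}

#' Collapse mutation calls to a gene-by-strain incidence matrix
#'
#' Coarse-grains mutation calls at the gene level: every call is assigned to
#' its anchor gene (for multi-gene deletions and amplifications the anchor is
#' the "repeatable" gene supplied in the records; single-gene calls anchor to
#' themselves), a strain/gene cell is 1 if any qualifying call hit it, and
#' the number of distinct calls per cell is kept in a parallel count matrix
#' (several independent hits to one gene in one population are one incidence
#' but several counts). Identical duplicate records are dropped first, so the
#' result is invariant to record order and duplication.
#'
#' @param records mutation record data frame. Multi-gene events are rows
#'   whose `gene` lists several genes separated by `";"`; they must carry a
#'   non-missing `anchor_gene`.
#' @param strain_meta optional data frame (`strain_id`, plus metadata such as
#'   `lineage`, `regime`, `strategy`) declaring the full strain universe;
#'   strains without calls then appear as all-zero columns.
#' @param gene_universe optional character vector declaring genes that must
#'   appear as rows even with no calls.
#' @return object of class `incidence_matrix`: list with binary `incidence`
#'   (genes x strains), integer `counts`, and `strain_meta`.
#' @export
collapse_to_gene <- function(records, strain_meta = NULL,
                             gene_universe = NULL) {
  records <- validate_mutation_records(records)
  records <- unique(records)
  if (nrow(records) > 0) {
    multi <- grepl(";", records$gene, fixed = TRUE)
    anchor <- if ("anchor_gene" %in% names(records)) records$anchor_gene
              else rep(NA_character_, nrow(records))
    unresolved <- multi & (is.na(anchor) | anchor == "")
    if (any(unresolved))
      stop_config("multi-gene events without an anchor gene: %s",
                  paste(unique(records$gene[unresolved]), collapse = "; "))
    records$.anchor <- ifelse(is.na(anchor) | anchor == "",
                              records$gene, anchor)
  }
  strains <- sort(unique(c(records$strain_id, strain_meta$strain_id)))
  genes <- sort(unique(c(records$.anchor, gene_universe)))
  counts <- matrix(0L, length(genes), length(strains),
                   dimnames = list(genes, strains))
  if (nrow(records) > 0) {
    tab <- table(factor(records$.anchor, levels = genes),
                 factor(records$strain_id, levels = strains))
    counts[] <- as.integer(tab)
  }
  if (!is.null(strain_meta)) {
    missing <- setdiff(strains, strain_meta$strain_id)
    if (length(missing))
      stop_config("strain_meta lacks metadata for: %s",
                  paste(missing, collapse = ", "))
    strain_meta <- strain_meta[match(strains, strain_meta$strain_id), ,
                               drop = FALSE]
  }
  structure(list(incidence = (counts > 0) + 0L, counts = counts,
                 strain_meta = strain_meta),
            class = "incidence_matrix")
}

#' Per-generation mutation rates
#'
#' Normalizes per-strain mutation counts by the generations each strain
#' experienced.
#'
#' @param counts named numeric vector of mutation counts per strain.
#' @param generations named numeric vector of total generations per strain
#'   (same names, all > 0).
#' @return named vector of mutations per generation.
#' @export
per_generation_rate <- function(counts, generations) {
  if (is.null(names(counts)) || !all(names(counts) %in% names(generations)))
    stop_config("counts and generations must be named by strain and match")
  generations <- generations[names(counts)]
  if (any(generations <= 0)) stop_config("generations must be positive")
  counts / generations
}

#' Two-sample t-test on per-strain rates between groups
#'
#' @param rates named numeric vector (e.g. from [per_generation_rate()]).
#' @param grouping named factor/character with exactly two levels.
#' @param welch use the Welch statistic instead of pooled variance.
#' @return list with `t_stat`, `df`, `p_value` and the group means.
#' @export
rate_group_test <- function(rates, grouping, welch = FALSE) {
  grouping <- grouping[names(rates)]
  g <- factor(grouping)
  if (nlevels(g) != 2) stop_config("grouping must have exactly two levels")
  means <- tapply(rates, g, mean)
  if (stats::sd(rates) == 0) {
    # equal counts over equal generations everywhere: no evidence either way
    return(list(t_stat = 0, df = length(rates) - 2, p_value = 1,
                means = means))
  }
  ht <- stats::t.test(rates ~ g, var.equal = !welch)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, means = means)
}

#' Gene-level mutation-incidence enrichment between two strain groups
#'
#' For every gene mutated in at least `min_strains` strains overall, compares
#' the incidence proportions of the two groups with a pooled two-proportion
#' z-test, `z = (p1 - p2) / sqrt(p*(1-p*)(1/n1 + 1/n2))` with `p*` the pooled
#' proportion, and controls the false discovery rate across tested genes by
#' Benjamini-Hochberg.
#'
#' @param im an [collapse_to_gene()] incidence matrix.
#' @param grouping either the name of a `strain_meta` column or a named
#'   vector over strains; must define exactly two non-empty groups.
#' @param min_strains minimum total incidence for a gene to be tested.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (directions refer to the first group level).
#' @return data frame with one row per tested gene: counts, `z`, `p_value`,
#'   `fdr_q`.
#' @export
z_enrichment <- function(im, grouping, min_strains = 3,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(im, "incidence_matrix"))
  g <- resolve_grouping(im, grouping)
  lev <- levels(g)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop_config("grouping must define two non-empty groups")
  inc <- im$incidence
  test_genes <- rownames(inc)[rowSums(inc) >= min_strains]
  if (length(test_genes) == 0)
    return(data.frame(gene = character(), k1 = integer(), n1 = integer(),
                      k2 = integer(), n2 = integer(), z_stat = numeric(),
                      p_value = numeric(), fdr_q = numeric()))
  n1 <- sum(g == lev[1]); n2 <- sum(g == lev[2])
  k1 <- rowSums(inc[test_genes, g == lev[1], drop = FALSE])
  k2 <- rowSums(inc[test_genes, g == lev[2], drop = FALSE])
  pbar <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (k1 / n1 - k2 / n2) / se, 0)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  out <- data.frame(gene = test_genes, k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                    z_stat = z, p_value = p, fdr_q = bh_fdr(p),
                    row.names = NULL)
  out[order(out$p_value), ]
}

resolve_grouping <- function(im, grouping) {
  strains <- colnames(im$incidence)
  if (is.character(grouping) && length(grouping) == 1 &&
      !is.null(im$strain_meta) && grouping %in% names(im$strain_meta)) {
    g <- im$strain_meta[[grouping]][match(strains, im$strain_meta$strain_id)]
  } else {
    if (is.null(names(grouping)) || !all(strains %in% names(grouping)))
      stop_config("grouping must cover every strain in the matrix")
    g <- grouping[strains]
  }
  factor(as.character(g))
}

#' Mann-Whitney U comparison of per-strain mutation counts
#'
#' Compares per-strain counts (of a mutation class or functional category)
#' between two groups. For combined sample sizes up to `exact_max` the
#' p-value is exact: the U statistic is computed on mid-ranks and its null
#' distribution enumerated over all group assignments, which handles ties
#' correctly. Larger samples use the normal approximation with tie and
#' continuity corrections. If every value is tied across both groups the
#' comparison is degenerate and p = 1 is returned with a flag.
#'
#' @param x,y numeric vectors of per-strain counts (each length >= 3).
#' @param alternative `"two.sided"`, `"less"` (x tends smaller) or
#'   `"greater"` (x tends larger).
#' @param exact_max largest combined n for which the exact enumeration runs.
#' @return list with `U` (for the first group), `p_value`, `exact`,
#'   `degenerate`.
#' @export
class_count_compare <- function(x, y,
                                alternative = c("two.sided", "less", "greater"),
                                exact_max = 20) {
  alternative <- match.arg(alternative)
  if (length(x) < 3 || length(y) < 3)
    stop_config("each group needs at least 3 strains")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y)) # mid-ranks
  w_obs <- sum(r[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  if (stats::sd(c(x, y)) == 0)
    return(list(U = u_obs, p_value = 1, exact = TRUE, degenerate = TRUE))
  if (n <= exact_max) {
    sums <- utils::combn(n, n1, FUN = function(i) sum(r[i]))
    p_le <- mean(sums <= w_obs)
    p_ge <- mean(sums >= w_obs)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(U = u_obs, p_value = p, exact = TRUE, degenerate = FALSE))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  cc <- 0.5
  z_le <- (u_obs - mu + cc) / sqrt(sigma2)
  z_ge <- (u_obs - mu - cc) / sqrt(sigma2)
  p <- switch(alternative,
              less = stats::pnorm(z_le),
              greater = stats::pnorm(z_ge, lower.tail = FALSE),
              two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                         stats::pnorm(z_ge, lower.tail = FALSE))))
  list(U = u_obs, p_value = p, exact = FALSE, degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate q-values
#'
#' Step-up q-values; monotone in the sorted p-values and never below the
#' input p-value's rank ordering.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop_config("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
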