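records_fixture <- function() {
  data.frame(
    strain_id = c("A", "A", "A", "B", "B", "C"),
    sample_kind = "population",
    gene = c("rho", "lon", "lon", "rho", "cybB;hokB;mokB;trg", "nadR"),
    anchor_gene = c(NA, NA, NA, NA, "cybB", NA),
    mutation_class = c("nonsynonymous", "intergenic", "small_indel",
                       "nonsynonymous", "large_deletion", "nonsynonymous"),
    frequency = c(0.9, 0.5, 0.3, 1, 0.8, 0.06),
    position = 1:6)
}

test_that("frequency filtering keeps the 5% boundary and spares clone calls", {
  rec <- data.frame(strain_id = "A", sample_kind = "population",
                    gene = "g", mutation_class = "nonsynonymous",
                    frequency = c(0.04, 0.05, 0.9))
  kept <- filter_by_frequency(rec)
  expect_equal(kept$frequency, c(0.05, 0.9))
  clones <- rec; clones$sample_kind <- "clone"; clones$frequency <- 1
  expect_equal(nrow(filter_by_frequency(clones)), 3)
  expect_equal(nrow(filter_by_frequency(rec[0, ])), 0)
  expect_equal(filter_by_frequency(rec, 1)$frequency, numeric(0))
  fixed <- rec; fixed$frequency <- c(0.5, 1, 1)
  expect_equal(nrow(filter_by_frequency(fixed, 1)), 2)
  expect_error(filter_by_frequency(rec, 0), "0, 1")
  expect_error(filter_by_frequency(rec, 1.5), "0, 1")
})

test_that("gene collapsing separates incidence from multiplicity and anchors multi-gene events", {
  im <- collapse_to_gene(records_fixture())
  expect_s3_class(im, "incidence_matrix")
  # two distinct lon mutations in strain A: incidence 1, count 2
  expect_equal(im$incidence["lon", "A"], 1)
  expect_equal(im$counts["lon", "A"], 2)
  # the 4-gene deletion collapses to its anchor
  expect_true("cybB" %in% rownames(im$incidence))
  expect_false(any(grepl(";", rownames(im$incidence))))
  expect_equal(im$incidence["cybB", "B"], 1)
  expect_true(all(im$incidence %in% 0:1))
})

test_that("collapsing is invariant to record order and duplication", {
  rec <- records_fixture()
  a <- collapse_to_gene(rec)
  b <- collapse_to_gene(rec[sample.int(nrow(rec)), ])
  d <- collapse_to_gene(rbind(rec, rec))
  expect_identical(a$incidence, b$incidence)
  expect_identical(a$incidence, d$incidence)
  expect_identical(a$counts, d$counts)
})

test_that("collapsing errors and edge cases behave", {
  rec <- records_fixture()
  rec$anchor_gene[5] <- NA
  expect_error(collapse_to_gene(rec), "anchor")
  empty <- collapse_to_gene(records_fixture()[0, ],
                            gene_universe = c("g1", "g2"),
                            strain_meta = data.frame(strain_id = c("A", "B")))
  expect_equal(dim(empty$incidence), c(2, 2))
  expect_true(all(empty$incidence == 0))
  expect_error(collapse_to_gene(records_fixture(),
                                strain_meta = data.frame(strain_id = "A")),
               "lacks metadata")
})

test_that("per-generation rates are plain arithmetic with validation", {
  expect_equal(unname(per_generation_rate(c(A = 12), c(A = 600))), 0.02)
  expect_error(per_generation_rate(c(A = 1), c(A = 0)), "positive")
  rates <- per_generation_rate(c(A = 2, B = 3, C = 5, D = 4),
                               c(A = 100, B = 100, C = 100, D = 100))
  gt <- rate_group_test(rates, c(A = "g1", B = "g1", C = "g2", D = "g2"))
  expect_equal(gt$p_value, stats::t.test(c(2, 3) / 100, c(5, 4) / 100,
                                         var.equal = TRUE)$p.value)
  # equal counts over equal generations in both groups: t = 0, p = 1
  same <- rate_group_test(c(A = 1, B = 1, C = 1, D = 1) /
                            c(A = 10, B = 10, C = 10, D = 10),
                          c(A = "g1", B = "g1", C = "g2", D = "g2"))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
})

test_that("rate comparison detects a doubled Poisson rate with high power", {
  set.seed(8)
  hits <- replicate(400, {
    r1 <- stats::rpois(12, 10) / 500
    r2 <- stats::rpois(12, 20) / 500
    names(r1) <- paste0("a", 1:12); names(r2) <- paste0("b", 1:12)
    rate_group_test(c(r1, r2),
                    stats::setNames(rep(c("g1", "g2"), each = 12),
                                    c(names(r1), names(r2))))$p_value < 0.05
  })
  expect_gt(mean(hits), 0.90)
})

test_that("z enrichment matches the hand-computed pooled two-proportion test", {
  strains <- c(paste0("x", 1:12), paste0("y", 1:12))
  rec <- data.frame(strain_id = paste0("x", 1:9), sample_kind = "population",
                    gene = "hit", mutation_class = "nonsynonymous",
                    frequency = 1)
  meta <- data.frame(strain_id = strains,
                     group = rep(c("g1", "g2"), each = 12))
  im <- collapse_to_gene(rec, strain_meta = meta)
  res <- z_enrichment(im, "group", min_strains = 3)
  # 9/12 vs 0/12: pbar = 0.375, z = 0.75 / sqrt(0.375*0.625/6)
  expect_equal(res$z_stat, 0.75 / sqrt(0.375 * 0.625 / 6), tolerance = 1e-12)
  expect_equal(res$z_stat, 3.7947, tolerance = 1e-4)
  expect_equal(res$p_value, 1.47e-4, tolerance = 0.02)
  # z^2 equals the uncorrected chi-square statistic (independent route)
  chi <- suppressWarnings(stats::prop.test(c(9, 0), c(12, 12),
                                           correct = FALSE))
  expect_equal(res$z_stat^2, unname(chi$statistic), tolerance = 1e-9)
})

test_that("z enrichment applies the three-strain rule and the null is flat", {
  strains <- c(paste0("x", 1:12), paste0("y", 1:12))
  rec <- rbind(
    data.frame(strain_id = c("x1", "y1"), sample_kind = "population",
               gene = "rare", mutation_class = "nonsynonymous", frequency = 1),
    data.frame(strain_id = c(paste0("x", 1:6), paste0("y", 1:6)),
               sample_kind = "population", gene = "even",
               mutation_class = "nonsynonymous", frequency = 1))
  meta <- data.frame(strain_id = strains,
                     group = rep(c("g1", "g2"), each = 12))
  res <- z_enrichment(collapse_to_gene(rec, strain_meta = meta), "group")
  expect_false("rare" %in% res$gene) # only 2 strains, excluded
  expect_equal(res$z_stat[res$gene == "even"], 0)
  expect_equal(res$p_value[res$gene == "even"], 1)
  expect_error(z_enrichment(collapse_to_gene(rec, strain_meta = meta),
                            c(x1 = "a")), "cover every strain")
})

test_that("enrichment p-values are uniform under a label-permutation null", {
  set.seed(21)
  cfg <- synthetic_mutation_config(
    paste0("g", 1:12),
    groups = list(g1 = paste0("s", 1:12), g2 = paste0("s", 13:24)),
    prob = matrix(0.5, 12, 2, dimnames = list(paste0("g", 1:12),
                                              c("g1", "g2"))))
  ps <- unlist(lapply(1:80, function(s) {
    tab <- generate_mutation_table(cfg, seed = s)
    meta <- data.frame(strain_id = paste0("s", 1:24),
                       group = sample(rep(c("a", "b"), 12)))
    im <- collapse_to_gene(tab, strain_meta = meta,
                           gene_universe = paste0("g", 1:12))
    z_enrichment(im, "group")$p_value
  }))
  # discrete p-values: check uniformity loosely via the mean and tail mass
  expect_equal(mean(ps), 0.5, tolerance = 0.1)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("Mann-Whitney exact p matches full enumeration and the textbook case", {
  r <- class_count_compare(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / 20)
  set.seed(33)
  for (i in 1:12) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- sample(0:3, n1, replace = TRUE) # ties on purpose
    y <- sample(0:4, n2, replace = TRUE)
    if (stats::sd(c(x, y)) == 0) next
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(class_count_compare(x, y, alternative = alt)$p_value,
                   oracle_mw(x, y, alternative = alt), tolerance = 1e-9,
                   info = paste(alt, paste(x, collapse = ","),
                                paste(y, collapse = ",")))
    }
  }
})

test_that("Mann-Whitney agrees with wilcox.test on tie-free data and handles degeneracy", {
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.4, 2.9, 1.1, 0.7)
  expect_equal(class_count_compare(x, y, "two.sided")$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-9)
  same <- class_count_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.5)
  tied <- class_count_compare(c(2, 2, 2), c(2, 2, 2))
  expect_true(tied$degenerate)
  expect_equal(tied$p_value, 1)
  # large samples switch to the normal approximation with tie and continuity
  # corrections, matching wilcox.test's approximation
  set.seed(4)
  bx <- stats::rpois(15, 3); by <- stats::rpois(15, 4)
  big <- class_count_compare(bx, by, "two.sided")
  expect_false(big$exact)
  ref <- suppressWarnings(stats::wilcox.test(bx, by, exact = FALSE,
                                             correct = TRUE))
  expect_equal(big$p_value, ref$p.value, tolerance = 1e-9)
  big_l <- class_count_compare(bx, by, "less")
  ref_l <- suppressWarnings(stats::wilcox.test(bx, by, exact = FALSE,
                                               correct = TRUE,
                                               alternative = "less"))
  expect_equal(big_l$p_value, ref_l$p.value, tolerance = 1e-9)
})

test_that("BH q-values match hand computation and preserve ordering", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(12)
  for (i in 1:10) {
    p <- stats::runif(sample(3:20, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # rank order preserved
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("planted enrichment is recovered as the top hit by FDR", {
  genes <- paste0("g", 1:15)
  groups <- list(g1 = paste0("s", 1:12), g2 = paste0("s", 13:24))
  prob <- matrix(0.2, 15, 2, dimnames = list(genes, names(groups)))
  prob["g1", ] <- c(0.8, 0)
  cfg <- synthetic_mutation_config(genes, groups, prob)
  meta <- data.frame(strain_id = unlist(groups),
                     group = rep(c("g1", "g2"), each = 12))
  top <- vapply(1:60, function(s) {
    tab <- generate_mutation_table(cfg, seed = s)
    im <- collapse_to_gene(tab, strain_meta = meta, gene_universe = genes)
    res <- z_enrichment(im, "group")
    res$gene[which.min(res$fdr_q)]
  }, "")
  expect_gte(mean(top == "g1"), 0.95)
})

test_that("the mutation generator honours degenerate configurations", {
  genes <- c("a", "b")
  groups <- list(g1 = c("s1", "s2"), g2 = c("s3", "s4"))
  sure <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(genes, names(groups)))
  tab <- generate_mutation_table(
    synthetic_mutation_config(genes, groups, sure), seed = 1)
  expect_equal(sort(unique(tab$strain_id)), c("s1", "s2"))
  expect_equal(nrow(tab), 4) # both genes in both g1 strains
  none <- matrix(0, 2, 2, dimnames = list(genes, names(groups)))
  expect_equal(nrow(generate_mutation_table(
    synthetic_mutation_config(genes, groups, none), seed = 1)), 0)
  expect_error(synthetic_mutation_config(character(), groups, none),
               "empty")
  expect_identical(generate_mutation_table(default_mutation_config(), seed = 9),
                   generate_mutation_table(default_mutation_config(), seed = 9))
})
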