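test_that("the default layout partitions the plate and normalization yields 92 features", {
  layout <- gen3_layout()
  expect_equal(nrow(layout), 96)
  expect_equal(sort(as.integer(table(layout$role))), sort(c(70, 1, 22, 1, 2)))
  set.seed(2)
  od <- runif(96, 0, 2)
  f <- normalize_plate(od, layout)
  expect_length(f, 92)
  expect_equal(sum(grepl("^met_", names(f))), 70)
  expect_equal(sum(grepl("^chem_", names(f))), 22)
})

test_that("normalization subtracts the controls and cancels plate offsets", {
  layout <- gen3_layout()
  od <- rep(0.3, 96) # every metabolic well equals the negative control
  od[layout$well[layout$role == "positive_control"]] <- 1.1
  f <- normalize_plate(od, layout)
  expect_true(all(f[grepl("^met_", names(f))] == 0))
  expect_true(all(f[grepl("^chem_", names(f))] == 1.1 - 0.3))
  set.seed(3)
  od2 <- runif(96)
  expect_equal(normalize_plate(od2 + 0.37, layout), normalize_plate(od2, layout),
               tolerance = 1e-12)
  expect_error(normalize_plate(od2[1:95], layout), "96")
})

test_that("zero-noise zero-effect plates normalize to identical vectors", {
  cfg <- default_biolog_config(effect_size = 0, noise_sd = 1e-12)
  pl <- generate_biolog_plates(cfg, seed = 1)
  f <- normalize_plates(pl, pl$layout)
  anc <- f[pl$meta$temperature_C == 37, ]
  expect_lt(max(abs(sweep(anc, 2, anc[1, ]))), 1e-9)
})

test_that("the default Biolog design yields 252 plates with complete metadata", {
  pl <- generate_biolog_plates(default_biolog_config(), seed = 2)
  expect_equal(nrow(pl$od), 252)
  expect_equal(sum(pl$meta$role == "evolved"), 24 * 3 * 3)
  expect_equal(sum(pl$meta$role == "ancestor"), 2 * 3 * 6)
  expect_false(anyNA(pl$od))
  expect_false(any(pl$meta$plate_id == ""))
  expect_error(default_biolog_config(reps_evolved = 1), "at least 2")
  expect_error(default_biolog_config(effect_size = -1), "non-negative")
})

test_that("imputation replaces a gross outlier well by the replicate mean", {
  cfg <- default_biolog_config()
  pl <- generate_biolog_plates(cfg, seed = 4)
  rows <- which(pl$meta$strain_id == "S606-2" & pl$meta$temperature_C == 15)
  well <- 10
  good <- mean(pl$od[rows[2:3], well])
  pl$od[rows[1], well] <- 10 * pl$od[rows[1], well]
  fixed <- qc_impute(pl)
  expect_equal(unname(fixed$od[rows[1], well]), good, tolerance = 1e-9)
  expect_true(any(fixed$imputed$plate_id == pl$meta$plate_id[rows[1]] &
                    fixed$imputed$well == well))
  # untouched wells stay untouched
  expect_equal(fixed$od[rows[2], ], pl$od[rows[2], ])
})

test_that("clean replicate sets pass through imputation unchanged", {
  pl <- generate_biolog_plates(default_biolog_config(), seed = 5)
  fixed <- qc_impute(pl)
  expect_equal(nrow(fixed$imputed), 0)
  expect_identical(fixed$od, pl$od)
})

test_that("two-replicate sets need explicit flags and impute the other replicate's value", {
  od <- matrix(rep(runif(96), 2), 2, byrow = TRUE)
  od[1, 5] <- od[1, 5] + 3
  rownames(od) <- c("p1", "p2")
  plates <- list(od = od, meta = data.frame(plate_id = c("p1", "p2"),
                                            strain_id = "s",
                                            temperature_C = 15,
                                            replicate = 1:2,
                                            role = "evolved"))
  expect_error(qc_impute(plates), "supply flags")
  fixed <- qc_impute(plates, flags = data.frame(plate_id = "p1", well = 5))
  expect_equal(unname(fixed$od[1, 5]), unname(od[2, 5]))
  expect_error(qc_impute(plates, flags = data.frame(plate_id = c("p1", "p2"),
                                                    well = 5)),
               "all replicates")
})

test_that("centering is exact, idempotent and validates feature names", {
  set.seed(6)
  m <- matrix(rnorm(5 * 92), 5, 92,
              dimnames = list(NULL, paste0("f", 1:92)))
  cen <- assemble_and_center(m)
  expect_lt(max(abs(colMeans(cen))), 1e-12)
  twice <- assemble_and_center(cen)
  expect_equal(unclass(twice)[, ], unclass(cen)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  one <- assemble_and_center(m[1, , drop = FALSE])
  expect_true(all(one == 0))
  vecs <- list(a = setNames(rnorm(3), c("x", "y", "z")),
               b = setNames(rnorm(3), c("x", "z", "y")))
  expect_error(assemble_and_center(vecs), "inconsistent")
})

test_that("broken-stick values match the closed form", {
  expect_equal(broken_stick(3), c(11 / 18, 5 / 18, 2 / 18), tolerance = 1e-12)
  expect_equal(broken_stick(1), 1)
  expect_equal(sum(broken_stick(10)), 1, tolerance = 1e-12)
})

test_that("PCA reports a valid spectrum and auto-selection finds 3 strong directions", {
  set.seed(7)
  n <- 120
  q <- qr.Q(qr(matrix(rnorm(92 * 3), 92, 3)))
  signal <- matrix(rnorm(n * 3, sd = sqrt(10)), n, 3) %*% t(q)
  x <- signal + matrix(rnorm(n * 92), n, 92)
  m <- fit_pca(assemble_and_center(x), "auto")
  expect_equal(m$retained, 3)
  expect_equal(sum(m$prop_var), 1, tolerance = 1e-9)
  expect_true(all(diff(m$eigenvalues) <= 1e-9))
  expect_error(fit_pca(x[1:2, ]), "3 samples")
  low_rank <- matrix(rnorm(5 * 92), 5, 92)
  expect_error(fit_pca(low_rank, n_components = 10), "rank")
})

test_that("ancestor centroids equal replicate means (k-means with k = 1)", {
  pl <- generate_biolog_plates(default_biolog_config(), seed = 8)
  feats <- assemble_and_center(normalize_plates(pl, pl$layout))
  m <- fit_pca(feats, 3)
  cents <- ancestor_centroids(m, pl$meta, by = "lineage")
  expect_equal(nrow(cents), 6) # 2 lineages x 3 temperatures
  i <- which(cents$group == "606" & cents$temperature_C == 37)
  sel <- pl$meta$role == "ancestor" & pl$meta$lineage == "606" &
    pl$meta$temperature_C == 37
  expect_equal(unlist(cents[i, c("PC1", "PC2", "PC3")], use.names = FALSE),
               unname(colMeans(m$scores[sel, 1:3])), tolerance = 1e-9)
  pooled <- ancestor_centroids(m, pl$meta, by = "pooled")
  expect_equal(nrow(pooled), 3)
  # order invariance
  perm <- sample(nrow(pl$od))
  m2 <- m; m2$scores <- m$scores[perm, ]
  cents2 <- ancestor_centroids(m2, pl$meta[perm, ], by = "lineage")
  j <- which(cents2$group == "606" & cents2$temperature_C == 37)
  expect_equal(cents2$PC1[j], cents$PC1[i], tolerance = 1e-12)
})

test_that("Ward clustering separates planted blobs and is order invariant", {
  set.seed(9)
  blob <- function(center, n) sweep(matrix(rnorm(n * 92), n, 92), 2, center, "+")
  c1 <- rep(0, 92); c2 <- rep(0, 92); c2[1:10] <- 10
  x <- rbind(blob(c1, 8), blob(c2, 8))
  rownames(x) <- paste0("s", 1:16)
  cl <- cluster_samples(x, k = 2)
  truth <- rep(1:2, each = 8)
  expect_true(all(table(cl$labels, truth) %in% c(0, 8))) # perfect agreement
  expect_match(cl$newick, "^\\(")
  perm <- sample(16)
  cl2 <- cluster_samples(x[perm, ], k = 2)
  expect_equal(sort(cl2$hclust$height), sort(cl$hclust$height),
               tolerance = 1e-9)
  dup <- x; rownames(dup) <- rep("a", 16)
  expect_error(cluster_samples(dup), "duplicate")
})

test_that("the most displaced temperature splits off first in the ancestor dendrogram", {
  pl <- generate_biolog_plates(default_biolog_config(), seed = 10)
  anc <- pl$meta$role == "ancestor"
  feats <- assemble_and_center(normalize_plates(pl, pl$layout)[anc, ])
  cl <- cluster_samples(feats, k = 2)
  # the 43 C condition has the largest ancestral displacement: the first
  # split should isolate it from the 15/37 C plates
  tab <- table(cl$labels, pl$meta$temperature_C[anc])
  hot_cluster <- which.max(tab[, "43"])
  expect_equal(unname(tab[hot_cluster, "43"]), sum(tab[, "43"]))
  expect_equal(sum(tab[hot_cluster, c("15", "37")]), 0)
})

test_that("temperature dominates the first principal component of the synthetic design", {
  hits <- vapply(1:20, function(s) {
    pl <- generate_biolog_plates(default_biolog_config(), seed = s)
    m <- fit_pca(assemble_and_center(normalize_plates(pl, pl$layout)), 3)
    pc1 <- m$scores[, 1]
    anc <- pl$meta$role == "ancestor"
    hot <- anc & pl$meta$temperature_C == 43
    rest <- anc & pl$meta$temperature_C != 43
    gap <- abs(mean(pc1[hot]) - mean(pc1[rest]))
    spread <- stats::sd(c(pc1[hot] - mean(pc1[hot]),
                          pc1[rest] - mean(pc1[rest])))
    gap > 3 * spread
  }, NA)
  expect_gte(mean(hits), 0.95)
})
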