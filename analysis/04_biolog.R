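#!/usr/bin/env Rscript
# Stage 4: phenotype-microarray restoration analysis.
#
# The full synthetic Biolog GEN III design (24 evolved clones in triplicate
# plus the two founders in six replicates, at 15/37/43 C = 252 plates) is
# generated with planted restoration categories, processed (normalization to
# the control wells, dye wells dropped, replicate QC imputation, centering),
# embedded with PCA, and each strain's response at each stress temperature is
# classified into the seven-way restoration scheme relative to the founder's
# states at the stress temperature and at the 37 C optimum. Group-level
# Fisher and Mann-Whitney comparisons follow, plus Ward clustering.

library(fluctevo)

seed <- 20211022
out <- "results"
dir.create(out, showWarnings = FALSE)

config <- default_biolog_config()
plates <- generate_biolog_plates(config, seed = derive_seed(seed, "biolog"))
plates <- qc_impute(plates)
cat(sprintf("%d plates, %d imputed wells\n", nrow(plates$od),
            nrow(plates$imputed)))

feats <- normalize_plates(plates, plates$layout)
centered <- assemble_and_center(feats)
write_tsv(data.frame(plate_id = rownames(centered), centered,
                     check.names = FALSE),
          file.path(out, "04_feature_matrix.tsv"))

model <- fit_pca(centered, n_components = 3)
print(model)
write_tsv(data.frame(plate_id = rownames(model$scores),
                     model$scores[, 1:model$retained]),
          file.path(out, "04_pca_scores.tsv"))

calls <- classify_restoration(model, plates$meta, alpha = 0.05)
write_tsv(calls, file.path(out, "04_restoration_calls.tsv"))
write_tsv(attr(calls, "summary"), file.path(out, "04_restoration_summary.tsv"))

cat("headline restoration calls by temperature:\n")
print(table(attr(calls, "summary")$headline,
            attr(calls, "summary")$temperature_C))

# recovery against the planted truth
rec <- recover_planted_restoration(plates)
cat(sprintf("planted-category recovery: %.1f%% of %d calls\n",
            100 * mean(rec$recovered), nrow(rec)))

# group tests: 15 vs 43 C, and restorative-planted strains vs the rest
planted <- config$planted
restorative_ids <- unique(planted$strain_id[planted$category %in%
  c("restored", "partially_restored", "over_restored")])
grouping <- stats::setNames(
  ifelse(unique(calls$strain_id) %in% restorative_ids,
         "a_restorative_planted", "b_other"),
  unique(calls$strain_id))
tests <- restoration_group_tests(calls, grouping = grouping,
                                 alternative = "greater")
write_tsv(tests, file.path(out, "04_restoration_group_tests.tsv"))
print(tests)

# Ward/Euclidean clustering of all phenotype vectors
cl <- cluster_samples(centered, k = 2)
writeLines(cl$newick, file.path(out, "04_dendrogram.nwk"))
cat("top split vs assay temperature:\n")
print(table(cl$labels, plates$meta$temperature_C))
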