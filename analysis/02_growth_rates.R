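#!/usr/bin/env Rscript
# Stage 2: growth-rate characterization and strategy classification.
#
# Replicate growth curves of every evolved clone and its founder are
# simulated at 15 and 43 C with planted rate changes (periodic-regime strains
# mostly gain at both temperatures, random-regime strains at one). Rates are
# estimated from the curves, each clone is compared to its founder with the
# pooled-variance two-sample t-test, and strains are classified as
# generalist / specialist / not-significant. Group-level follow-ups: Fisher
# exact enrichment of generalists in the periodic regimes and the F-test on
# relative-growth-rate variances.

library(fluctevo)

seed <- 20211022
out <- "results"
dir.create(out, showWarnings = FALSE)

design <- simulate_experiment(n_cycles = 0, seed = 1)$design
effects <- default_growth_effects(design)
assay <- generate_growth_assay(effects, seed = derive_seed(seed, "assay"))
analysis <- assay_strategy_analysis(assay, alpha = 0.05)

write_tsv(analysis$estimates, file.path(out, "02_growth_rate_estimates.tsv"))
write_tsv(analysis$results, file.path(out, "02_relative_growth.tsv"))
write_tsv(analysis$strategies, file.path(out, "02_strategy_calls.tsv"))

strategies <- analysis$strategies
regime <- design$regime[match(strategies$strain_id, design$culture_id)]
periodic <- regime %in% c("slow", "fast")
gen <- strategies$category == "generalist"

cat("strategy calls by regime type:\n")
print(table(ifelse(periodic, "periodic", "random"), strategies$category))

fisher_p <- fisher_strategy_enrichment(matrix(
  c(sum(gen & periodic), sum(!gen & periodic),
    sum(gen & !periodic), sum(!gen & !periodic)), 2))
cat(sprintf("generalist enrichment in periodic regimes: Fisher p = %.3g\n",
            fisher_p))

for (tm in c(15, 43)) {
  r <- analysis$results[analysis$results$temperature_C == tm, ]
  p_idx <- periodic[match(r$strain_id, strategies$strain_id)]
  vr <- variance_ratio_test(r$ratio[p_idx], r$ratio[!p_idx])
  cat(sprintf("relative-growth variance periodic vs random at %d C: F = %.2f, p = %.3g\n",
              tm, vr$F, vr$p_value))
}

# Fig-2-style scatter of relative growth rates
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  gg <- ggplot(strategies, aes(ratio_15, ratio_43, colour = category)) +
    geom_point(size = 2) +
    geom_hline(yintercept = 1, linetype = 3) +
    geom_vline(xintercept = 1, linetype = 3) +
    labs(x = "relative growth rate at 15 C",
         y = "relative growth rate at 43 C",
         colour = "strategy") +
    theme_bw()
  ggsave(file.path(out, "02_relative_growth_scatter.pdf"), gg,
         width = 6, height = 4.5)
}
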