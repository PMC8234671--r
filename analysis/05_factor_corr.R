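#!/usr/bin/env Rscript
# Step 5 -- Pearson correlation between R/G ratios and the chromatin-factor
# panel (BH-adjusted), and rank-sum association of ratios with the planted
# mutation flag.

library(rgratio)

out <- "results/corr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

profiles <- read.delim("results/stratify/rg_profiles.tsv")
meta <- read_sample_metadata("results/sim/metadata.tsv")
fx <- read.delim("results/sim/factor_expr.tsv", check.names = FALSE)
expr <- as.matrix(fx[, -1])
rownames(expr) <- fx$factor
tiers <- read.delim("results/sim/factor_tiers.tsv")

rg <- setNames(profiles$rg_ratio, profiles$sample)
panel <- correlate_panel(rg[colnames(expr)], expr)
panel$tier <- tiers$tier[match(panel$factor, tiers$factor)]
write.table(panel, file.path(out, "factor_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (t in unique(panel$tier)) {
  cat(sprintf("tier %-5s mean PCC = %+.2f (%s)\n", t,
              mean(panel$pcc[panel$tier == t]),
              paste(panel$factor[panel$tier == t], collapse = ", ")))
}

mut <- mutation_association(rg[meta$sample], meta$mut_RUNX1)
write.table(data.frame(mutation = "RUNX1", statistic = mut$statistic,
                       p = mut$p, exact = mut$exact, n_mut = mut$n1,
                       n_wt = mut$n0),
            file.path(out, "mutation_associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "RUNX1 mutation vs R/G ratio: W = %.0f, p = %.4g (%s, %d mutated / %d wild-type).\n",
  mut$statistic, mut$p, if (mut$exact) "exact" else "approximate",
  mut$n1, mut$n0))
cat("Wrote correlation panel and mutation associations to", out, "\n")
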