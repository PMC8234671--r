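#!/usr/bin/env Rscript
# Step 3 -- between-stratum differential expression: NB Wald contrasts of
# high-vs-mid and low-vs-mid with per-contrast BH adjustment, the strict
# baseMean > 100 / |log2FC| > 1 / padj < 0.05 filter, and MA tables.

library(rgratio)

out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_count_table("results/sim/counts.tsv")
profiles <- read.delim("results/stratify/rg_profiles.tsv")
sf <- size_factors(tab)
strata <- setNames(profiles$stratum, profiles$sample)

for (contrast in list(c("high", "mid"), c("low", "mid"))) {
  cname <- paste0(contrast[1], "_vs_", contrast[2])
  gB <- names(strata)[strata == contrast[1]]
  gA <- names(strata)[strata == contrast[2]]
  res <- nb_wald_test(tab, sf, gA, gB)
  sig <- significance_filter(res)
  write.table(res, file.path(out, paste0("de_", cname, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sig, file.path(out, paste0("significant_", cname, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ma_table(res), file.path(out, paste0("ma_", cname, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_rep <- sum(res$kind == "repeat" & res$significant)
  cat(sprintf(
    "%s: %d vs %d samples; %d features pass the significance filter (%d repeats, %d up / %d down).\n",
    cname, length(gB), length(gA), nrow(sig), n_rep,
    sum(sig$log2FoldChange > 0), sum(sig$log2FoldChange < 0)))
}
cat("Wrote DE tables, filtered lists and MA tables to", out, "\n")
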