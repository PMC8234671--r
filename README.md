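# rgratio

Repeat-to-gene expression ratio analysis for AML transcriptomes.

Bulk RNA-seq of acute myeloid leukemia (AML) captures transcripts from
annotated repeat elements — SINE/ALU, LINE, LTR/ERV, satellites, DNA
transposons — alongside genes, and how de-repressed that repeat compartment
is varies strongly between patients. `rgratio` condenses this into one
per-sample statistic, the **R/G ratio**

```
R/G(sample) = median over repeat features of normalized expression
            / median over gene features of normalized expression
```

stratifies a cohort into **low / mid / high-repeat** subgroups by
equal-interval binning of the z-scored ratios, and carries the strata
through the downstream questions a clinical cohort poses: which features
are differentially expressed between strata (negative-binomial Wald test,
Benjamini–Hochberg FDR, strict baseMean > 100 / |log2FC| > 1 /
padj < 0.05 filter), whether the strata differ in survival (Kaplan–Meier,
log-rank, multivariate Cox with age, gender and cytogenetic risk), and
which chromatin factors track the ratio (Pearson + BH panel, rank-sum
association with mutation flags). Input is the TEtranscripts joint
gene+repeat count-table dialect (repeat rows named
`subfamily:family:class`).

Because the patient cohorts that motivate the method are access-restricted,
the package ships a negative-binomial cohort simulator
(`simulate_cohort()`) with planted repeat-expression groups, survival
effects and tiered factor correlations, so every stage is testable end to
end. It is first-class, tested code — the study conditions, not a fixture.

## Worked example

The five scripts under `analysis/` run the whole workflow on a simulated
60-sample cohort (3 planted groups x 20, seed 1) and narrate what they
find:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_ratio_stratify.R
Rscript analysis/03_diffexpr.R
Rscript analysis/04_survival.R
Rscript analysis/05_factor_corr.R
```

Step 2 prints:

```
R/G ratios span 0.83-1.05 across 60 samples.

 low  mid high
  20   20   20
Concordance with the planted groups: 100.0%.
```

— the equal-interval cut of the z-scored ratios recovers the three planted
groups exactly on this cohort. Step 4 prints:

```
Log-rank high- vs low-repeat: chi2 = 17.50, p = 2.875e-05 (49 events).
Low-repeat hazard ratio vs mid: 4.74 (95% CI 2.18-10.32, p = 8.95e-05).
```

— low-repeat patients carry the planted excess hazard (they are the
high-risk group), while the high-repeat hazard ratio stays near 1 against
the mid stratum and age/gender/cytogenetic risk contribute nothing, as
planted. Step 5 prints:

```
tier high  mean PCC = +0.79 (POU5F2, ASH1L, BAZ2B, ATRX)
tier mid   mean PCC = +0.33 (SUV39H1, EHMT2, TRIM28, DAXX)
tier none  mean PCC = -0.10 (SETDB1, CBX5, DNMT1, CHAF1A)
```

— the three correlation tiers planted at 0.8 / 0.4 / 0 are recovered from
the computed ratios.

The same pipeline runs on real data by pointing `run_pipeline()` at a
count table and metadata file instead of the simulator; see
`?run_pipeline` and `?default_config`.

## Layout

```
R/                  package code: IO, normalization, R/G stratification,
                    NB Wald DE, survival, factor correlation, simulator,
                    pipeline orchestration
analysis/           numbered workflow drivers (simulate -> stratify -> DE
                    -> survival -> correlation), writing under results/
scripts/acceptance.R   headline-quantity reproduction script
tests/testthat/     unit, property and acceptance tests with brute-force
                    oracles
vignettes/          methods vignette: model, parameters, design choices
inst/extdata/       the 12-factor chromatin panel list
```
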