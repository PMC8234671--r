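---
title: "The R/G ratio: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The R/G ratio: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgratio)
```

## The statistic

Acute myeloid leukemia (AML) transcriptomes express annotated repeat
elements — SINE/ALU, LINE, LTR/ERV, satellite and DNA-transposon derived
transcripts — alongside genes, and the overall level of that repeat
compartment varies strongly between patients. The package's core statistic
condenses this into one number per sample, the repeat-to-gene expression
ratio:

$$
\mathrm{R/G}_s \;=\;
\frac{\operatorname{median}_{f \in \text{repeats}} x_{fs}}
     {\operatorname{median}_{f \in \text{genes}} x_{fs}},
$$

where \(x_{fs}\) is normalized log2-scale expression. Because both medians
run over thousands of features, the ratio is a robust, library-size-free
summary of how de-repressed the repeat compartment is relative to the gene
compartment. Cohorts are then z-scored and split into *low*, *mid* and
*high*-repeat strata by equal-interval binning of the ratio (equal range,
not equal count), and the strata drive every downstream analysis:
differential expression, survival, and chromatin-factor correlation.

Two conventions apply everywhere: the median of an even number of values is
the mean of the two central values, and medians are taken over **all**
annotated features of a kind, including zero-count rows. The latter is a
genuine modelling choice — dropping all-zero rows shifts both medians — so
`rg_profile(use_features = "nonzero")` exposes the alternative and the
choice is recorded in the result's provenance attribute.

## Input dialect and normalization

Count tables follow the TEtranscripts joint gene+repeat dialect: repeat
rows are `subfamily:family:class` triples (exactly two colons), gene rows
are colon-free identifiers. Anything else is rejected rather than guessed.

Normalization is median-of-ratios size factors followed by
`log2(count/sf + pseudocount)`. The shifted log is a deliberate surrogate
for regularized-log or variance-stabilizing transforms: the R/G ratio
depends only on two medians, which the fine shape of the transform barely
moves, and a transparent transform keeps every downstream number auditable.
The pseudocount (default 1, so zero maps to zero) is configurable; the
transform name and pseudocount are stored in the matrix's provenance
attribute. Features containing a zero in any sample are excluded from the
size-factor median only — never from the normalized matrix. With no feature
positive in every sample the median-of-ratios reference is undefined and
`size_factors()` refuses to proceed rather than silently switching to a
pseudo-reference.

## Stratification

`cut_interval(values, n = 3)` splits the observed range into three
equal-width, right-closed bins (`low`, `mid`, `high`); an exact interior
edge belongs to the lower bin and the first bin is closed at the minimum.
Equal-interval binning was preferred over quantile cut-points because it
imposes no target group sizes: a cohort with one extreme sample will get a
one-sample stratum, which is the honest description of that cohort.
Equal-range bins are affine-invariant, so cutting z-scores and cutting raw
ratios give identical strata; the z-scores are computed (sample sd,
divisor \(n-1\)) because they are the scale on which strata are reported.
When all ratios are equal the range carries no information and every sample
is labelled `mid` rather than inventing extremes. Stratification is always
performed within one cohort at a time; ratio ranges are not comparable
across cohorts normalized with different transforms.

## Differential expression between strata

`nb_wald_test()` is a deliberately plain negative-binomial Wald surrogate,
not a reimplementation of a full DE framework. Per feature, with normalized
counts \(y = c/\mathrm{sf}\) and group means \(\bar y_A, \bar y_B\):

* fold change: \(\log_2\!\big((\bar y_B + \varepsilon)/(\bar y_A +
  \varepsilon)\big)\), with \(\varepsilon\) = half the smallest positive
  normalized count (configurable) to keep zero-mean features finite;
* variance model: \(\operatorname{Var}(y) = \mu/\mathrm{sf} + \alpha\mu^2\);
  the dispersion \(\alpha\) is estimated per feature by method of moments,
  floored at \(10^{-8}\), and moderated toward the across-feature median
  with a fixed prior weight of 20 pseudo-degrees of freedom. The moderation
  matters: at 10-vs-10 sample sizes the raw per-feature moment estimator is
  noisy enough to push the nominal 5% test to a ~7% empirical type-I error,
  while the moderated estimator sits near 6% (known dispersion gives ~5%).
  The prior weight is a fixed constant, not fitted;
* the Wald statistic (fold change over its delta-method standard error) is
  referred to the standard normal. Features with zero counts in both groups
  carry no information and are assigned p = 1.

The test is validated by simulation — null calibration and planted
fold-change recovery — rather than by matching any reference tool's output.
Contrasts are strictly two-group (high-vs-mid, low-vs-mid against the mid
stratum); covariate-adjusted designs are out of scope. BH adjustment is
applied per contrast. The downstream significance filter is strict on all
three thresholds: baseMean > 100 normalized reads, |log2FC| > 1,
adjusted p < 0.05.

## Survival

Kaplan–Meier estimation, the log-rank test and the multivariate Cox model
stand on the `survival` package behind the module's interface: product-limit
curves per stratum, the observed-minus-expected chi-square on pooled event
times, and a proportional-hazards fit with Efron tie handling (Breslow via
`ties = "breslow"`). Categorical covariates are dummy-coded against declared
reference levels — `mid` for the stratum (so both directions of the repeat
effect are read off one fit), `favorable` for cytogenetic risk — and age
enters continuously. Records with missing covariates are dropped with a
reported count. Warnings that indicate an untrustworthy fit (monotone
likelihood, non-convergence) are promoted to errors; the 95% intervals are
Wald, \(\exp(\hat\beta \pm 1.96\,\mathrm{se})\). Proportional-hazards
diagnostics are intentionally not provided.

## Factor correlation and mutation association

Pearson correlation with a t-reference (n − 2 df) relates per-sample R/G
ratios to each chromatin factor's expression; BH adjustment runs across the
panel. The shipped panel (`inst/extdata/chromatin_factors.tsv`) lists the
twelve factors used throughout: four expected to track the ratio strongly
(POU5F2, ASH1L, BAZ2B, ATRX), four moderately (SUV39H1, EHMT2, TRIM28,
DAXX) and four not at all (SETDB1, CBX5, DNMT1, CHAF1A); any user list is
accepted.

Mutation association uses the two-sided Wilcoxon rank-sum test, exact by
full enumeration whenever the smaller group has at most eight samples and
there are no ties — the regime where small AML mutation subgroups live —
and the tie- and continuity-corrected normal approximation otherwise.

## The cohort simulator

`simulate_cohort()` produces cohorts with exactly the structure the
analysis assumes, so each stage can be tested end to end without patient
data:

* **Counts.** Feature means are log-normal (meanlog `log(200)`, sdlog 1.5 —
  a heavy-tailed expression distribution typical of bulk RNA-seq); counts
  are NB with dispersion α = 0.1 and log-normal library factors
  (σ = 0.2). Repeat class means are rescaled so expected read shares hit
  the composition targets (SINE 40%, LINE 30%, LTR 9%, satellite 0.2%, DNA
  transposons the remainder) and repeats contribute ~10% of all reads in a
  mid-level sample.
* **Planted groups.** Three groups of 20 samples whose repeat rows are
  globally scaled by 0.6 / 1.0 / 1.5. These scalings are generator
  defaults chosen so the resulting R/G ratios span roughly 0.83–1.05 after
  the default transform — comparable to the spread reported in real AML
  cohorts — and are tunable, not empirical estimates.
* **Survival.** Exponential event times with hazard
  \(h_0 e^{\beta\,[\text{group}=\text{low}]}\); defaults
  \(h_0 = 1/1000\) per day, β = 1 (low-repeat patients fare worse, the
  direction observed clinically) and exponential censoring at rate 1/2500.
* **Factors.** Each factor in tier t is
  \(8 + 1.5(\rho_t z + \sqrt{1-\rho_t^2}\,e)\) with z the standardized
  ratio signal, so the population Pearson correlation equals the tier
  target (0.8 / 0.4 / 0).
* **Mutations.** A planted binary flag (`mut_RUNX1`) enriched in the
  high-repeat group (30% vs 5%).

All randomness derives from one seed via fixed per-stage offsets, so adding
features cannot perturb sample-level draws and a fixed seed reproduces
every byte. What the generator does **not** emulate: multimapper ambiguity
between repeat copies, per-class dispersion differences, batch structure,
correlated gene modules, and non-proportional hazards. Tests passing on
simulated cohorts therefore demonstrate that the pipeline recovers the
structure it assumes — not that real AML cohorts satisfy those assumptions.

## Numerical choices and problem sizes

Degenerate inputs fail loudly and early: zero gene median, zero variance
before a correlation or z-score, no events before a log-rank test, constant
covariates in a Cox model. Ties in equal-interval binning go to the lower
bin; medians of even-length vectors average the central pair; the BH
adjustment is the textbook step-up.

The validation suite runs at deliberately desk-sized problems: 20 cohorts
of 60 samples for stratification recovery, 1000-feature 10-vs-10 null and
planted simulations for DE calibration, 200 replicates for log-rank power
at hazard ratio 3, 500 replicates of n = 200 for Cox effect recovery, and
n = 120 cohorts for the correlation tiers. These sizes keep every property
estimate's Monte-Carlo error well inside the tolerance it is checked
against.

## Limitations

* The transform is a documented surrogate; per-feature normalized values
  differ from regularized-log output even though the R/G ratio is stable.
* The DE surrogate has no covariate adjustment and no fold-change
  shrinkage; at very small counts its normal-reference Wald p-values are
  approximate.
* Cohort-level clinical numbers from patient datasets (stratum sizes,
  specific p-values, hazard indices) depend on restricted data and are not
  reproduced here; the simulator mirrors their direction and structure
  only.
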