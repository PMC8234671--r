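#' Simulation configuration for synthetic AML-like cohorts
#'
#' Defaults describe the cohort structure the analysis assumes: three planted
#' repeat-expression groups (low/mid/high) of 20 samples each; negative
#' binomial counts (variance `mu + alpha mu^2`) with log-normal feature means
#' and per-sample library-size variation; a repeat compartment whose class
#' composition targets the read shares observed in AML transcriptomes
#' (SINE ~40%, LINE ~30%, LTR/ERV ~9%, satellites ~0.2%, DNA transposons the
#' remainder) and whose overall level is globally scaled per planted group
#' (0.6 / 1.0 / 1.5); exponential survival with a higher hazard for the
#' low-repeat group (low repeat = worse prognosis); and a chromatin-factor
#' panel with tiered population correlation (0.8 / 0.4 / 0) to the R/G ratio.
#'
#' @param n_per_group named integer vector, samples per planted group.
#' @param n_genes number of gene features.
#' @param n_repeats_per_class named integer vector, repeat features per class.
#' @param class_fractions named vector of target read shares per repeat class
#'   (among repeat reads; must sum to 1).
#' @param repeat_total_fraction target share of all reads that are
#'   repeat-derived in a mid (scaling 1) sample.
#' @param repeat_scaling named positive vector, global repeat scaling per
#'   planted group.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param libsize_sigma sd of log-normal per-sample library factors.
#' @param gene_mean_meanlog,gene_mean_sdlog log-normal parameters of feature
#'   base means.
#' @param baseline_hazard exponential event hazard per day for non-low
#'   groups.
#' @param log_hr_low log hazard ratio of the low-repeat group versus the
#'   rest (positive = low-repeat patients fare worse).
#' @param censor_rate exponential censoring hazard per day (0 = none).
#' @param tier_pcc named vector of target population Pearson correlations
#'   per factor tier.
#' @param factor_tiers named list mapping tier name to factor gene symbols.
#' @param mutation_prob named vector: probability of the planted `mut_RUNX1`
#'   flag per group (associated with the high-repeat group).
#' @param seed integer RNG seed; all randomness derives from it.
#' @return list of class `rg_sim_config`.
#' @export
sim_config <- function(n_per_group = c(low = 20, mid = 20, high = 20),
                       n_genes = 2000,
                       n_repeats_per_class = c(SINE = 120, LINE = 90, LTR = 60,
                                               Satellite = 20, DNA = 60),
                       class_fractions = c(SINE = 0.40, LINE = 0.30,
                                           LTR = 0.09, Satellite = 0.002,
                                           DNA = 0.208),
                       repeat_total_fraction = 0.10,
                       repeat_scaling = c(low = 0.6, mid = 1.0, high = 1.5),
                       dispersion = 0.1,
                       libsize_sigma = 0.2,
                       gene_mean_meanlog = log(200),
                       gene_mean_sdlog = 1.5,
                       baseline_hazard = 1 / 1000,
                       log_hr_low = 1.0,
                       censor_rate = 1 / 2500,
                       tier_pcc = c(high = 0.8, mid = 0.4, none = 0),
                       factor_tiers = list(
                         high = c("POU5F2", "ASH1L", "BAZ2B", "ATRX"),
                         mid = c("SUV39H1", "EHMT2", "TRIM28", "DAXX"),
                         none = c("SETDB1", "CBX5", "DNMT1", "CHAF1A")),
                       mutation_prob = c(low = 0.05, mid = 0.05, high = 0.30),
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "rg_sim_config")
  violations <- validate_sim_config(cfg)
  if (length(violations)) {
    stop("invalid simulation config:\n  - ",
         paste(violations, collapse = "\n  - "))
  }
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg an `rg_sim_config` or plain list with the same fields.
#' @return character vector of violations (empty when valid).
#' @export
validate_sim_config <- function(cfg) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(all(cfg$n_per_group >= 1), "n_per_group entries must be >= 1")
  chk(setequal(names(cfg$n_per_group), c("low", "mid", "high")),
      "n_per_group must name groups low, mid, high")
  chk(cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(all(cfg$n_repeats_per_class >= 1), "n_repeats_per_class entries must be >= 1")
  chk(all(cfg$class_fractions >= 0 & cfg$class_fractions <= 1),
      "class_fractions must lie in [0, 1]")
  chk(abs(sum(cfg$class_fractions) - 1) < 1e-9 ||
        sum(cfg$class_fractions) <= 1,
      "class_fractions must sum to at most 1")
  chk(setequal(names(cfg$n_repeats_per_class), names(cfg$class_fractions)),
      "class_fractions and n_repeats_per_class must name the same classes")
  chk(cfg$repeat_total_fraction > 0 && cfg$repeat_total_fraction < 1,
      "repeat_total_fraction must lie in (0, 1)")
  chk(all(cfg$repeat_scaling > 0), "repeat_scaling entries must be positive")
  chk(cfg$dispersion > 0, "dispersion must be positive")
  chk(cfg$libsize_sigma >= 0, "libsize_sigma must be non-negative")
  chk(cfg$baseline_hazard > 0, "baseline_hazard must be positive")
  chk(cfg$censor_rate >= 0, "censor_rate must be non-negative")
  chk(all(cfg$tier_pcc >= -1 & cfg$tier_pcc <= 1), "tier_pcc must lie in [-1, 1]")
  chk(setequal(names(cfg$factor_tiers), names(cfg$tier_pcc)),
      "factor_tiers and tier_pcc must name the same tiers")
  chk(all(cfg$mutation_prob >= 0 & cfg$mutation_prob <= 1),
      "mutation_prob must lie in [0, 1]")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed must be a single number")
  v
}

# fixed sub-stream offsets: feature-level, sample-level, count, survival,
# factor and mutation draws each get their own seed so that e.g. adding
# features does not perturb sample-level draws
sim_seed_offsets <- c(features = 101L, samples = 211L, counts = 307L,
                      survival = 401L, factors = 503L, mutation = 601L)

sim_repeat_naming <- list(
  SINE = c(prefix = "AluY.s", family = "Alu"),
  LINE = c(prefix = "L1M.s", family = "L1"),
  LTR = c(prefix = "LTR12.s", family = "ERVL"),
  Satellite = c(prefix = "ALR.s", family = "centr"),
  DNA = c(prefix = "Tigger.s", family = "TcMar"))

#' Simulate a joint repeat+gene count table with planted groups
#'
#' Feature base means are log-normal. Repeat means are rescaled per class so
#' that expected class read shares match `class_fractions` and the expected
#' repeat share of all reads in a mid sample equals `repeat_total_fraction`.
#' Counts are NB with per-sample library factors; repeat rows of a sample in
#' planted group g are additionally scaled by `repeat_scaling[g]`. Output is
#' byte-identical for a given seed.
#'
#' @param cfg an `rg_sim_config`.
#' @return list with `table` (an `rg_count_table`), `meta` (metadata stub:
#'   sample, gender, age, cytogenetic_risk, subtype), and `truth` (list of
#'   `samples` and `features` data.frames describing the planted state).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "rg_sim_config") || is.list(cfg))
  violations <- validate_sim_config(cfg)
  if (length(violations)) {
    stop("invalid simulation config:\n  - ",
         paste(violations, collapse = "\n  - "))
  }
  classes <- names(cfg$n_repeats_per_class)
  unknown <- setdiff(classes, names(sim_repeat_naming))
  if (length(unknown)) stop("no naming scheme for class(es): ",
                            paste(unknown, collapse = ", "))

  # feature-level stream
  set.seed(cfg$seed + sim_seed_offsets[["features"]])
  gene_means <- stats::rlnorm(cfg$n_genes, cfg$gene_mean_meanlog,
                              cfg$gene_mean_sdlog)
  gene_ids <- sprintf("ENSG%08d", seq_len(cfg$n_genes))
  rep_ids <- character(0); rep_class <- character(0); rep_means <- numeric(0)
  total_repeat <- cfg$repeat_total_fraction / (1 - cfg$repeat_total_fraction) *
    sum(gene_means)
  frac <- cfg$class_fractions / sum(cfg$class_fractions)
  for (cl in classes) {
    n_c <- cfg$n_repeats_per_class[[cl]]
    raw <- stats::rlnorm(n_c, cfg$gene_mean_meanlog, cfg$gene_mean_sdlog)
    raw <- raw * (frac[[cl]] * total_repeat / sum(raw))
    nm <- sim_repeat_naming[[cl]]
    rep_ids <- c(rep_ids, sprintf("%s%03d:%s:%s", nm[["prefix"]], seq_len(n_c),
                                  nm[["family"]], cl))
    rep_class <- c(rep_class, rep(cl, n_c))
    rep_means <- c(rep_means, raw)
  }
  ids <- c(gene_ids, rep_ids)
  means <- c(gene_means, rep_means)
  is_repeat <- c(rep(FALSE, cfg$n_genes), rep(TRUE, length(rep_ids)))

  # sample-level stream
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(groups)
  samples <- sprintf("S%03d", seq_len(n))
  set.seed(cfg$seed + sim_seed_offsets[["samples"]])
  lib <- exp(stats::rnorm(n, 0, cfg$libsize_sigma))
  gender <- sample(c("F", "M"), n, replace = TRUE)
  age <- pmin(pmax(round(stats::rnorm(n, 55, 12)), 18), 90)
  risk <- sample(c("favorable", "intermediate", "adverse"), n, replace = TRUE,
                 prob = c(0.3, 0.5, 0.2))
  subtype <- sample(c("M1", "M2", "M4"), n, replace = TRUE)

  # count stream
  set.seed(cfg$seed + sim_seed_offsets[["counts"]])
  scaling <- cfg$repeat_scaling[groups]
  mu <- outer(means, lib)
  mu[is_repeat, ] <- sweep(mu[is_repeat, , drop = FALSE], 2, scaling, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   nrow = nrow(mu), dimnames = list(ids, samples))
  storage.mode(counts) <- "integer"

  features <- parse_feature_ids(ids)
  meta <- data.frame(sample = samples, gender = gender, age = age,
                     cytogenetic_risk = risk, subtype = subtype,
                     stringsAsFactors = FALSE)
  truth <- list(
    samples = data.frame(sample = samples, group = groups,
                         lib_factor = lib, repeat_scaling = unname(scaling),
                         stringsAsFactors = FALSE),
    features = data.frame(feature_id = ids,
                          kind = ifelse(is_repeat, "repeat", "gene"),
                          repeat_class = features$repeat_class,
                          true_mean = means, stringsAsFactors = FALSE))
  list(table = new_count_table(counts, features), meta = meta, truth = truth)
}

#' Simulate survival outcomes for planted groups
#'
#' Exponential event times with hazard
#' `baseline_hazard * exp(log_hr_low * [group == "low"])` and independent
#' exponential censoring; with `censor_rate = 0` every record is an event.
#'
#' @param truth_samples data.frame with `sample` and `group` columns (the
#'   `truth$samples` element of [simulate_counts()]).
#' @param cfg an `rg_sim_config`.
#' @return data.frame with `sample`, `survival_time` (days), `event` (0/1).
#' @export
simulate_survival <- function(truth_samples, cfg) {
  stopifnot(all(c("sample", "group") %in% colnames(truth_samples)))
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  n <- nrow(truth_samples)
  set.seed(cfg$seed + sim_seed_offsets[["survival"]])
  hazard <- cfg$baseline_hazard *
    exp(cfg$log_hr_low * (truth_samples$group == "low"))
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, rate = cfg$censor_rate)
            else rep(Inf, n)
  data.frame(sample = truth_samples$sample,
             survival_time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Simulate chromatin-factor expression with tiered correlation
#'
#' Each factor in tier t is `8 + 1.5 * (rho_t z + sqrt(1 - rho_t^2) e)` with
#' `z` the standardized R/G ratios and `e` standard normal noise, so the
#' population Pearson correlation with the ratio equals the tier target
#' `rho_t`.
#'
#' @param rg per-sample R/G ratios (planted or computed), named or aligned
#'   with the cohort.
#' @param cfg an `rg_sim_config`.
#' @return list with `expr` (factors x samples matrix) and `tiers`
#'   (data.frame factor, tier, target_pcc).
#' @export
simulate_factor_expression <- function(rg, cfg) {
  if (stats::sd(rg) == 0) stop("R/G ratios have zero variance")
  z <- (rg - mean(rg)) / stats::sd(rg)
  tiers <- names(cfg$factor_tiers)
  set.seed(cfg$seed + sim_seed_offsets[["factors"]])
  rows <- list(); tier_map <- list()
  for (t in tiers) {
    rho <- cfg$tier_pcc[[t]]
    for (f in cfg$factor_tiers[[t]]) {
      e <- stats::rnorm(length(z))
      rows[[f]] <- 8 + 1.5 * (rho * z + sqrt(1 - rho^2) * e)
      tier_map[[f]] <- data.frame(factor = f, tier = t, target_pcc = rho,
                                  stringsAsFactors = FALSE)
    }
  }
  expr <- do.call(rbind, rows)
  colnames(expr) <- names(rg)
  list(expr = expr, tiers = do.call(rbind, tier_map))
}

#' Simulate a full cohort
#'
#' Counts, metadata (including survival columns and a planted `mut_RUNX1`
#' flag enriched in the high-repeat group), factor expression tied to the
#' planted repeat scaling, and the ground truth.
#'
#' @param cfg an `rg_sim_config`.
#' @return list with `table`, `meta`, `factor_expr`, `factor_tiers`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  sim <- simulate_counts(cfg)
  surv <- simulate_survival(sim$truth$samples, cfg)
  sim$meta$survival_time <- surv$survival_time[match(sim$meta$sample, surv$sample)]
  sim$meta$event <- surv$event[match(sim$meta$sample, surv$sample)]
  set.seed(cfg$seed + sim_seed_offsets[["mutation"]])
  p_mut <- cfg$mutation_prob[sim$truth$samples$group]
  sim$meta$mut_RUNX1 <- stats::rbinom(nrow(sim$meta), 1, p_mut)
  # correlation tiers are anchored to the planted per-sample repeat level
  rg_planted <- stats::setNames(log2(sim$truth$samples$repeat_scaling),
                                sim$meta$sample)
  fac <- simulate_factor_expression(rg_planted, cfg)
  sim$factor_expr <- fac$expr
  sim$factor_tiers <- fac$tiers
  sim
}

#' Concordance between assigned strata and planted groups
#'
#' @param strata factor/character of assigned strata (`low`/`mid`/`high`).
#' @param groups character of planted groups, same order.
#' @return fraction of samples whose stratum equals their planted group.
#' @export
stratum_concordance <- function(strata, groups) {
  stopifnot(length(strata) == length(groups))
  mean(as.character(strata) == as.character(groups))
}
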