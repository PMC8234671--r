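#' Default pipeline configuration
#'
#' @param seed RNG seed used for every stochastic stage.
#' @param output_dir directory for tabular outputs and the manifest.
#' @return Named list describing a full run: input paths (or a simulation
#'   block), normalization settings, stratification bin count, differential
#'   expression thresholds, survival covariates with reference levels, and
#'   the chromatin-factor list.
#' @export
default_config <- function(seed = 1, output_dir = "results/run") {
  list(
    input = list(counts = NULL, metadata = NULL, factors = NULL),
    simulate = TRUE,
    sim = sim_config(seed = seed),
    pseudocount = 1,
    use_features = "all",
    stratify_n = 3,
    de = list(base_mean_min = 100, lfc_min = 1, padj_max = 0.05,
              dispersion_prior_weight = 20),
    survival = list(covariates = c("stratum", "age", "gender",
                                   "cytogenetic_risk"),
                    reference = list(stratum = "mid",
                                     cytogenetic_risk = "favorable"),
                    ties = "efron"),
    factor_list = NULL,
    seed = seed,
    output_dir = output_dir
  )
}

#' Validate a pipeline configuration
#'
#' @param config a config list as from [default_config()], or the path to a
#'   YAML file holding one (missing fields are filled from the defaults).
#' @return list with `valid` (logical), `violations` (character vector) and
#'   `config` (the completed configuration).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- default_config()
  config <- utils::modifyList(defaults, config)
  if (!inherits(config$sim, "rg_sim_config")) {
    config$sim <- do.call(sim_config,
                          config$sim[names(config$sim) %in%
                                       names(formals(sim_config))])
  }
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$pseudocount) && config$pseudocount > 0,
      "pseudocount must be positive")
  chk(config$use_features %in% c("all", "nonzero"),
      "use_features must be 'all' or 'nonzero'")
  chk(is.numeric(config$stratify_n) && config$stratify_n >= 2,
      "stratify_n must be >= 2")
  chk(config$de$base_mean_min > 0, "de.base_mean_min must be positive")
  chk(config$de$lfc_min > 0, "de.lfc_min must be positive")
  chk(config$de$padj_max > 0 && config$de$padj_max <= 1,
      "de.padj_max must lie in (0, 1]")
  chk(config$survival$ties %in% c("efron", "breslow"),
      "survival.ties must be 'efron' or 'breslow'")
  if (!isTRUE(config$simulate)) {
    chk(!is.null(config$input$counts), "input.counts required when not simulating")
    chk(!is.null(config$input$metadata), "input.metadata required when not simulating")
  }
  v <- c(v, validate_sim_config(config$sim))
  list(valid = !length(v), violations = v, config = config)
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full R/G ratio analysis
#'
#' Orchestrates counts -> normalization -> R/G profiles and stratification ->
#' class fractions -> between-stratum differential expression (high vs mid
#' and low vs mid, BH-adjusted per contrast) -> Kaplan-Meier / log-rank / Cox
#' survival comparison -> chromatin-factor correlation panel -> mutation
#' associations, writing every result as TSV under `config$output_dir` plus
#' a JSON manifest recording the configuration and the provenance switches
#' in effect. Stages whose inputs are absent (no survival columns, no factor
#' expression, no `mut_*` flags) are skipped with a warning; any stage error
#' aborts the run naming the stage.
#'
#' @param config configuration list or YAML path; see [default_config()] and
#'   [validate_config()].
#' @return Invisibly, a list with the main in-memory results (`profiles`,
#'   `class_fractions`, `de`, `survival`, `correlations`, `mutation`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = default_config()) {
  val <- validate_config(config)
  if (!val$valid) {
    stop("invalid configuration:\n  - ",
         paste(val$violations, collapse = "\n  - "))
  }
  config <- val$config
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  factor_expr <- NULL
  if (isTRUE(config$simulate)) {
    sim <- run_stage("simulate", simulate_cohort(config$sim))
    table <- sim$table; meta <- sim$meta; factor_expr <- sim$factor_expr
    write_tsv(sim$truth$samples, config$output_dir, "truth_samples.tsv")
  } else {
    table <- run_stage("read_counts", read_count_table(config$input$counts))
    meta <- run_stage("read_metadata",
                      read_sample_metadata(config$input$metadata))
    aligned <- run_stage("align", align_samples(table, meta))
    table <- aligned$table; meta <- aligned$meta
  }

  sf <- run_stage("size_factors", size_factors(table))
  norm <- run_stage("normalize",
                    normalize_log(table, sf, config$pseudocount))
  write_tsv(data.frame(feature_id = rownames(norm), norm,
                       check.names = FALSE), config$output_dir,
            "normalized_matrix.tsv")

  profiles <- run_stage("rg_profile",
                        rg_profile(norm, table$features, config$use_features))
  profiles <- run_stage("stratify", stratify_cohort(profiles))
  write_tsv(profiles, config$output_dir, "rg_profiles.tsv")

  fractions <- run_stage("class_fractions", class_fractions(table))
  write_tsv(fractions, config$output_dir, "class_fractions.tsv")

  strata <- stats::setNames(as.character(profiles$stratum), profiles$sample)
  de <- list()
  for (contrast in list(c("high", "mid"), c("low", "mid"))) {
    gB <- names(strata)[strata == contrast[1L]]
    gA <- names(strata)[strata == contrast[2L]]
    cname <- paste0(contrast[1L], "_vs_", contrast[2L])
    if (length(gA) < 2L || length(gB) < 2L) {
      warning("skipping DE contrast ", cname, ": a stratum has < 2 samples")
      next
    }
    res <- run_stage(paste0("de_", cname),
                     nb_wald_test(table, sf, gA, gB,
                                  dispersion_prior_weight =
                                    config$de$dispersion_prior_weight))
    de[[cname]] <- res
    write_tsv(res, config$output_dir, paste0("de_", cname, ".tsv"))
    write_tsv(significance_filter(res, config$de$base_mean_min,
                                  config$de$lfc_min, config$de$padj_max),
              config$output_dir, paste0("significant_", cname, ".tsv"))
    write_tsv(ma_table(res), config$output_dir, paste0("ma_", cname, ".tsv"))
  }

  surv_res <- NULL
  if (all(c("survival_time", "event") %in% colnames(meta)) &&
      any(!is.na(meta$survival_time))) {
    surv_res <- run_stage("survival", {
      rec <- data.frame(sample = meta$sample, time = meta$survival_time,
                        event = meta$event,
                        stratum = strata[meta$sample],
                        stringsAsFactors = FALSE)
      extra <- intersect(config$survival$covariates, colnames(meta))
      for (cov in setdiff(extra, "stratum")) rec[[cov]] <- meta[[cov]]
      rec <- rec[!is.na(rec$time), , drop = FALSE]
      km <- lapply(split(rec, rec$stratum), km_estimate)
      km_tab <- do.call(rbind, Map(function(s, d) {
        if (!nrow(d)) return(NULL)
        cbind(stratum = s, d)
      }, names(km), km))
      write_tsv(km_tab, config$output_dir, "km_curves.tsv")
      lr <- logrank_test(rec[rec$stratum == "high", ],
                         rec[rec$stratum == "low", ])
      write_tsv(data.frame(comparison = "high_vs_low", chi2 = lr$chi2,
                           p = lr$p), config$output_dir, "logrank.tsv")
      covs <- intersect(config$survival$covariates, colnames(rec))
      fit <- cox_fit(rec, covs, reference = config$survival$reference,
                     ties = config$survival$ties)
      write_tsv(forest_table(fit), config$output_dir, "cox_forest.tsv")
      list(km = km_tab, logrank = lr, cox = fit)
    })
  } else {
    warning("no survival columns in metadata; survival stage skipped")
  }

  if (is.null(factor_expr) && !is.null(config$input$factors)) {
    factor_list <- readLines(config$input$factors)
    factor_list <- factor_list[nzchar(factor_list)]
    present <- intersect(factor_list, rownames(norm))
    if (length(present)) factor_expr <- norm[present, , drop = FALSE]
  }
  corr_res <- NULL
  if (!is.null(factor_expr)) {
    corr_res <- run_stage("factor_correlation", {
      rg <- stats::setNames(profiles$rg_ratio, profiles$sample)
      correlate_panel(rg[colnames(factor_expr)], factor_expr)
    })
    write_tsv(corr_res, config$output_dir, "factor_correlations.tsv")
  } else {
    warning("no chromatin-factor expression available; correlation stage skipped")
  }

  mut_res <- NULL
  mut_cols <- grep("^mut_", colnames(meta), value = TRUE)
  if (length(mut_cols)) {
    mut_res <- run_stage("mutation_association", {
      rg <- stats::setNames(profiles$rg_ratio, profiles$sample)
      rows <- lapply(mut_cols, function(mc) {
        r <- mutation_association(rg[meta$sample], meta[[mc]])
        data.frame(mutation = sub("^mut_", "", mc), statistic = r$statistic,
                   p = r$p, exact = r$exact, n_mut = r$n1, n_wt = r$n0,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    write_tsv(mut_res, config$output_dir, "mutation_associations.tsv")
  }

  manifest <- list(
    package = "rgratio",
    version = as.character(utils::packageVersion("rgratio")),
    seed = config$seed,
    simulate = isTRUE(config$simulate),
    n_samples = length(table$samples),
    n_features = nrow(table$counts),
    stratum_counts = as.list(table(strata)),
    provenance = list(
      transform = "log2(count/sf + pseudocount)",
      pseudocount = config$pseudocount,
      use_features = config$use_features,
      stratify_n = config$stratify_n,
      de_thresholds = config$de,
      ties = config$survival$ties,
      median_rule = "even-length medians average the two central values"
    )
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(profiles = profiles, class_fractions = fractions, de = de,
                 survival = surv_res, correlations = corr_res,
                 mutation = mut_res, manifest = manifest))
}
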