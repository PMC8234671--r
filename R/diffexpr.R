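#' Two-group negative-binomial Wald test
#'
#' A transparent NB Wald surrogate for between-stratum differential
#' expression. Per feature, counts are size-factor normalized and the two
#' group means compared on the log2 scale:
#' `log2FC = log2((meanB + eps) / (meanA + eps))`, where the pseudo-mean
#' `eps` (default half the smallest positive normalized count in the table)
#' keeps fold changes finite at zero means. The standard error comes from the
#' NB variance model `Var(y) = mu/sf + alpha * mu^2` via the delta method;
#' the dispersion `alpha` is estimated per feature by method of moments and
#' moderated toward the across-feature median with a fixed prior weight
#' (per-feature moment estimates at typical group sizes are too noisy to
#' keep the test calibrated on their own). The Wald statistic
#' `log2FC / se` is referred to the standard normal; p-values are
#' BH-adjusted across all features of the contrast.
#'
#' Covariate adjustment is out of scope: contrasts are strictly two-group.
#'
#' @param table an `rg_count_table` or count matrix.
#' @param sf size factors for all samples of `table`.
#' @param groupA,groupB disjoint character vectors of sample names (each of
#'   size >= 2). Fold changes are reported as B over A.
#' @param eps pseudo-mean added to group means before taking log2; default
#'   `0.5 * min positive normalized count`.
#' @param dispersion_prior_weight prior weight (pseudo-degrees of freedom)
#'   pulling per-feature dispersion toward the panel median; default 20.
#' @return A data.frame with one row per feature: `feature_id`, `kind`,
#'   `repeat_class`, `baseMean` (mean of normalized counts over all samples
#'   of the table), `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`,
#'   `significant` (the expression/fold-change/FDR filter of
#'   [significance_filter()]). Provenance (eps, prior weight) is attached as
#'   an attribute.
#' @export
nb_wald_test <- function(table, sf, groupA, groupB, eps = NULL,
                         dispersion_prior_weight = 20) {
  counts <- if (inherits(table, "rg_count_table")) table$counts else table
  feats <- if (inherits(table, "rg_count_table")) {
    table$features
  } else {
    parse_feature_ids(rownames(counts))
  }
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("each group needs at least 2 samples")
  }
  missing <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
  if (length(sf) != ncol(counts)) stop("one size factor per table sample required")

  y <- sweep(counts, 2, sf, "/")
  baseMean <- rowMeans(y)
  yA <- y[, groupA, drop = FALSE]
  yB <- y[, groupB, drop = FALSE]
  nA <- length(groupA); nB <- length(groupB)
  mA <- rowMeans(yA); mB <- rowMeans(yB)
  vA <- apply(yA, 1, stats::var)
  vB <- apply(yB, 1, stats::var)

  # method-of-moments dispersion, pooled over the two groups, then moderated
  # toward the panel median: Var(y) = mu + alpha mu^2 (at sf = 1)
  a_raw <- ((nA - 1) * (vA - mA) / mA^2 + (nB - 1) * (vB - mB) / mB^2) /
    (nA + nB - 2)
  a_raw[!is.finite(a_raw)] <- 0
  a_raw <- pmax(a_raw, 0)
  a_med <- stats::median(a_raw)
  df <- nA + nB - 2
  alpha <- pmax((df * a_raw + dispersion_prior_weight * a_med) /
                  (df + dispersion_prior_weight), 1e-8)

  if (is.null(eps)) {
    pos <- y[y > 0]
    eps <- if (length(pos)) 0.5 * min(pos) else 0.5
  }
  if (eps <= 0) stop("eps must be positive")

  lfc <- log2((mB + eps) / (mA + eps))
  inv_sfA <- mean(1 / sf[match(groupA, colnames(counts))])
  inv_sfB <- mean(1 / sf[match(groupB, colnames(counts))])
  var_mA <- (mA * inv_sfA + alpha * mA^2) / nA
  var_mB <- (mB * inv_sfB + alpha * mB^2) / nB
  se <- sqrt(var_mA / (mA + eps)^2 + var_mB / (mB + eps)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(stat))
  # both groups all-zero: no information, not evidence for the null model
  nosignal <- mA == 0 & mB == 0
  pvalue[nosignal] <- 1
  padj <- bh_adjust(pvalue)

  res <- data.frame(feature_id = feats$feature_id, kind = feats$kind,
                    repeat_class = feats$repeat_class,
                    baseMean = unname(baseMean),
                    log2FoldChange = unname(lfc), lfcSE = unname(se),
                    stat = unname(stat), pvalue = unname(pvalue),
                    padj = unname(padj), stringsAsFactors = FALSE)
  res$significant <- res$baseMean > 100 & abs(res$log2FoldChange) > 1 &
    res$padj < 0.05
  attr(res, "provenance") <- list(eps = eps,
                                  dispersion_prior_weight = dispersion_prior_weight,
                                  contrast = c(A = paste(groupA, collapse = ","),
                                               B = paste(groupB, collapse = ",")))
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validating wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, order-aligned with the input, each `>=` its raw
#'   p-value and `<= 1`.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (anyNA(pvalues)) stop("p-values must not be NA")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Expression / fold-change / FDR significance filter
#'
#' The pathway-analysis input filter: keep features with baseMean strictly
#' above 100 normalized reads, `|log2FoldChange|` strictly above 1, and
#' BH-adjusted p strictly below 0.05. All three inequalities are strict.
#'
#' @param results data.frame from [nb_wald_test()].
#' @param base_mean_min,lfc_min,padj_max filter thresholds
#'   (defaults 100, 1, 0.05).
#' @return The filtered rows, reduced to `feature_id` and `log2FoldChange`
#'   (the pathway-tool-ready list), with the remaining statistics kept as
#'   extra columns.
#' @export
significance_filter <- function(results, base_mean_min = 100, lfc_min = 1,
                                padj_max = 0.05) {
  stopifnot(all(c("baseMean", "log2FoldChange", "padj") %in% colnames(results)))
  keep <- results$baseMean > base_mean_min &
    abs(results$log2FoldChange) > lfc_min &
    results$padj < padj_max
  out <- results[keep, , drop = FALSE]
  first <- c("feature_id", "log2FoldChange")
  out <- out[, c(first, setdiff(colnames(out), first)), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' MA table
#'
#' One row per feature with mean expression, fold change, adjusted p and a
#' class label (`repeat_class` for repeats, `"gene"` for genes), suitable for
#' external MA plotting.
#'
#' @param results data.frame from [nb_wald_test()].
#' @return data.frame with columns `feature_id`, `baseMean`,
#'   `log2FoldChange`, `padj`, `class_label`, `significant`.
#' @export
ma_table <- function(results) {
  needed <- c("feature_id", "kind", "repeat_class", "baseMean",
              "log2FoldChange", "padj", "significant")
  stopifnot(all(needed %in% colnames(results)))
  data.frame(feature_id = results$feature_id,
             baseMean = results$baseMean,
             log2FoldChange = results$log2FoldChange,
             padj = results$padj,
             class_label = ifelse(results$kind == "repeat",
                                  results$repeat_class, "gene"),
             significant = results$significant,
             stringsAsFactors = FALSE)
}
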