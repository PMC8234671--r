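#' Pearson correlation between R/G ratios and one factor's expression
#'
#' Standard Pearson r with a two-sided p-value from the t-distribution with
#' n - 2 degrees of freedom (via `stats::cor.test`).
#'
#' @param rg per-sample R/G ratios.
#' @param expr per-sample expression of one chromatin factor, same order.
#' @return list with `pcc`, `p`, `n`.
#' @export
pearson_corr <- function(rg, expr) {
  stopifnot(is.numeric(rg), is.numeric(expr))
  if (length(rg) != length(expr)) stop("series lengths differ")
  if (length(rg) < 3L) stop("Pearson correlation needs n >= 3")
  if (anyNA(rg) || anyNA(expr)) stop("series must not contain NA")
  if (stats::sd(rg) == 0) stop("zero variance in the R/G ratio series")
  if (stats::sd(expr) == 0) stop("zero variance in the expression series")
  ct <- stats::cor.test(rg, expr, method = "pearson", alternative = "two.sided")
  list(pcc = unname(ct$estimate), p = ct$p.value, n = length(rg))
}

#' Correlate R/G ratios with a panel of chromatin factors
#'
#' One Pearson correlation per factor, BH-adjusted across the panel. Factors
#' missing from the expression matrix are skipped with a warning.
#'
#' @param rg per-sample ratios, named by sample or aligned with the matrix
#'   columns.
#' @param expr_matrix factors x samples expression matrix with factor names
#'   as row names.
#' @param factors character vector of factor names to test; defaults to all
#'   rows of the matrix.
#' @return data.frame with columns `factor`, `pcc`, `p`, `padj`, `n`.
#' @export
correlate_panel <- function(rg, expr_matrix, factors = rownames(expr_matrix)) {
  stopifnot(is.matrix(expr_matrix))
  if (length(rg) != ncol(expr_matrix)) {
    stop("one ratio per expression-matrix column required")
  }
  present <- factors %in% rownames(expr_matrix)
  if (any(!present)) {
    warning("skipping factor(s) missing from the expression matrix: ",
            paste(factors[!present], collapse = ", "))
  }
  factors <- factors[present]
  if (!length(factors)) stop("no requested factor present in the matrix")
  res <- lapply(factors, function(f) {
    r <- pearson_corr(rg, expr_matrix[f, ])
    data.frame(factor = f, pcc = r$pcc, p = r$p, n = r$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out[, c("factor", "pcc", "p", "padj", "n")]
}

#' Rank-sum association between R/G ratios and a binary mutation flag
#'
#' Two-sided Wilcoxon rank-sum test of the ratios split by mutation status.
#' The p-value is exact (full enumeration of rank assignments) whenever the
#' smaller group has at most `exact_max` samples and there are no ties;
#' otherwise the normal approximation with tie and continuity correction is
#' used.
#'
#' @param rg per-sample R/G ratios.
#' @param mutation 0/1 flags, same order (1 = mutated).
#' @param exact_max largest minimum-group size for which the exact
#'   distribution is enumerated (default 8).
#' @return list with `statistic` (rank-sum W of the mutated group), `p`,
#'   `exact` (logical), and group sizes `n0`, `n1`.
#' @export
mutation_association <- function(rg, mutation, exact_max = 8) {
  stopifnot(length(rg) == length(mutation))
  keep <- !is.na(mutation) & !is.na(rg)
  rg <- rg[keep]; mutation <- mutation[keep]
  if (length(setdiff(mutation, c(0, 1)))) stop("mutation flags must be 0/1")
  x <- rg[mutation == 1]
  y <- rg[mutation == 0]
  if (!length(x) || !length(y)) {
    stop("both mutated and non-mutated groups must be nonempty")
  }
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact,
       n0 = length(y), n1 = length(x))
}
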