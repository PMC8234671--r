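#' Median-of-ratios size factors
#'
#' Library-size normalization in the DESeq style: each sample's factor is the
#' median, over features with strictly positive counts in every sample, of the
#' ratio of that sample's count to the feature's geometric mean across
#' samples. Features containing any zero are excluded from the median only;
#' they remain in the table and in every downstream matrix.
#'
#' @param table an `rg_count_table`, or a numeric count matrix
#'   (features x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#'   A single-sample table gets factor 1 by convention.
#' @export
#' @examples
#' m <- cbind(s1 = c(2, 4, 6), s2 = c(4, 8, 12))
#' size_factors(m)  # proportional 1:2
size_factors <- function(table) {
  counts <- if (inherits(table, "rg_count_table")) table$counts else table
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (ncol(counts) == 1L) {
    return(stats::setNames(1, colnames(counts)))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no feature has positive counts in every sample; median-of-ratios ",
         "is undefined (a pseudo-reference fallback is not implemented)")
  }
  lc <- log(counts[pos, , drop = FALSE])
  geo <- exp(rowMeans(lc))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col) {
    stats::median(col / geo)
  })
  stats::setNames(sf, colnames(counts))
}

#' Log-scale variance-stabilizing surrogate transform
#'
#' Normalized expression is `log2(count / size_factor + pseudocount)`. This
#' is a deliberate surrogate for regularized-log / variance-stabilizing
#' transforms: the downstream R/G statistic is a ratio of medians and is
#' insensitive to the fine shape of the transform, so a transparent
#' shifted-log is used and recorded in the result's provenance.
#'
#' @param table an `rg_count_table`, or a numeric count matrix.
#' @param sf size factors from [size_factors()]; computed from `table` when
#'   omitted.
#' @param pseudocount positive offset added after size-factor scaling
#'   (default 1, so a zero count maps to 0 on the log2 scale).
#' @return Numeric matrix, same shape and dimnames as the counts, with a
#'   `provenance` attribute recording the transform and pseudocount.
#' @export
normalize_log <- function(table, sf = size_factors(table), pseudocount = 1) {
  counts <- if (inherits(table, "rg_count_table")) table$counts else table
  stopifnot(is.matrix(counts))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  if (length(sf) != ncol(counts)) stop("one size factor per sample required")
  if (any(sf <= 0)) stop("size factors must be positive")
  norm <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  attr(norm, "provenance") <- list(transform = "log2(count/sf + pseudocount)",
                                   pseudocount = pseudocount)
  norm
}

#' Size-factor-normalized counts (linear scale)
#'
#' @param table an `rg_count_table` or count matrix.
#' @param sf size factors.
#' @return Numeric matrix of `count / size_factor`.
#' @export
normalized_counts <- function(table, sf = size_factors(table)) {
  counts <- if (inherits(table, "rg_count_table")) table$counts else table
  if (any(sf <= 0)) stop("size factors must be positive")
  sweep(counts, 2, sf, "/")
}
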