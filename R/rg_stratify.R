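#' Per-sample R/G ratio profiles
#'
#' The R/G ratio is the median normalized expression over all repeat features
#' divided by the median over all gene features, per sample. Medians are taken
#' over every annotated feature of each kind, including zero-count rows;
#' `use_features = "nonzero"` restricts both medians to features with nonzero
#' total count across the cohort. An even number of values yields the mean of
#' the two central values.
#'
#' @param norm normalized log2 expression matrix (features x samples), e.g.
#'   from [normalize_log()].
#' @param kinds per-feature `"gene"`/`"repeat"` tags, or a feature annotation
#'   data.frame with a `kind` column (as in `rg_count_table$features`).
#' @param use_features `"all"` (default) or `"nonzero"`.
#' @return A data.frame with one row per sample: `sample`,
#'   `median_repeat_expr`, `median_gene_expr`, `rg_ratio`. The choice of
#'   feature set is recorded in the `provenance` attribute.
#' @export
rg_profile <- function(norm, kinds, use_features = c("all", "nonzero")) {
  use_features <- match.arg(use_features)
  if (is.data.frame(kinds)) kinds <- kinds$kind
  stopifnot(length(kinds) == nrow(norm))
  keep <- rep(TRUE, nrow(norm))
  if (use_features == "nonzero") keep <- rowSums(abs(norm)) > 0
  rep_rows <- which(kinds == "repeat" & keep)
  gene_rows <- which(kinds == "gene" & keep)
  if (!length(rep_rows) || !length(gene_rows)) {
    stop("need at least one repeat and one gene feature")
  }
  med_r <- apply(norm[rep_rows, , drop = FALSE], 2, stats::median)
  med_g <- apply(norm[gene_rows, , drop = FALSE], 2, stats::median)
  if (any(med_g == 0)) {
    stop("median gene expression is zero for sample(s): ",
         paste(colnames(norm)[med_g == 0], collapse = ", "),
         " (degenerate normalization)")
  }
  out <- data.frame(sample = colnames(norm),
                    median_repeat_expr = unname(med_r),
                    median_gene_expr = unname(med_g),
                    rg_ratio = unname(med_r / med_g),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- list(use_features = use_features)
  out
}

#' z-score a numeric vector
#'
#' `(x - mean) / sd` with the sample standard deviation (divisor n - 1).
#'
#' @param values numeric vector, length >= 2, with positive spread.
#' @return z-scores with mean 0 and sample sd 1.
#' @export
zscore <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("z-score needs at least 2 values")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: all values equal, cannot z-score")
  (values - mean(values)) / s
}

#' Equal-interval binning
#'
#' Splits the observed range `[min, max]` into `n` contiguous bins of equal
#' width (equal range, not equal count). Bins are right-closed,
#' `(min + (k-1)w, min + kw]`, with the first bin additionally closed at the
#' minimum, matching the usual equal-interval cut convention. For `n = 3` the
#' labels are `low`, `mid`, `high`.
#'
#' If all values are equal the range carries no information and every value is
#' assigned the middle bin (`mid` for `n = 3`).
#'
#' @param values finite numeric vector.
#' @param n number of bins (default 3).
#' @param labels optional bin labels, length `n`, ordered low to high.
#' @return Factor of bin labels, one per value.
#' @export
#' @examples
#' cut_interval(c(0, 0.5, 1, 1.5, 2, 2.5, 3), 3)
cut_interval <- function(values, n = 3, labels = NULL) {
  if (!length(values)) stop("cut_interval: empty input")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  if (is.null(labels)) {
    labels <- if (n == 3) c("low", "mid", "high") else paste0("bin", seq_len(n))
  }
  stopifnot(length(labels) == n)
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    mid <- labels[[ceiling((n + 1) / 2)]]
    return(factor(rep(mid, length(values)), levels = labels))
  }
  breaks <- seq(rng[1L], rng[2L], length.out = n + 1)
  idx <- cut(values, breaks = breaks, labels = FALSE, include.lowest = TRUE,
             right = TRUE)
  factor(labels[idx], levels = labels)
}

#' Stratify a cohort by z-scored R/G ratios
#'
#' z-scores the cohort's R/G ratios and assigns each sample to the low, mid or
#' high-repeat stratum by equal-interval binning with `n = 3`. Equal-range
#' binning is affine-invariant, so the strata are identical whether the raw or
#' z-scored ratios are cut; the z-scores are kept because they are the scale
#' on which the strata are reported.
#'
#' @param profiles data.frame from [rg_profile()] (needs `sample` and
#'   `rg_ratio`).
#' @return The input with `zscore` and `stratum` columns added; `stratum` is a
#'   factor with levels `low`, `mid`, `high`.
#' @export
stratify_cohort <- function(profiles) {
  stopifnot(is.data.frame(profiles), "rg_ratio" %in% colnames(profiles))
  if (nrow(profiles) < 3L) stop("stratification needs at least 3 samples")
  if (stats::sd(profiles$rg_ratio) == 0) {
    profiles$zscore <- rep(0, nrow(profiles))
    profiles$stratum <- cut_interval(profiles$zscore, 3)
    return(profiles)
  }
  profiles$zscore <- zscore(profiles$rg_ratio)
  profiles$stratum <- cut_interval(profiles$zscore, 3)
  profiles
}

#' Repeat-class composition per sample
#'
#' Fractions of repeat-derived reads per repeat class (raw counts, i.e.
#' fractions of reads, not of normalized expression), plus the fraction of
#' all reads that are repeat-derived.
#'
#' @param table an `rg_count_table`.
#' @return A data.frame with one row per sample: `sample`, one
#'   `frac_<class>` column per repeat class present in the table (summing to
#'   1 per sample), and `repeat_fraction_of_all`. Every annotated class is
#'   reported as its own class; nothing is merged.
#' @export
class_fractions <- function(table) {
  stopifnot(inherits(table, "rg_count_table"))
  rep_idx <- table$features$kind == "repeat"
  rep_counts <- table$counts[rep_idx, , drop = FALSE]
  total_rep <- colSums(rep_counts)
  if (any(total_rep == 0)) {
    stop("zero repeat reads in sample(s): ",
         paste(table$samples[total_rep == 0], collapse = ", "))
  }
  classes <- sort(unique(table$features$repeat_class[rep_idx]))
  per_class <- sapply(classes, function(cl) {
    colSums(rep_counts[table$features$repeat_class[rep_idx] == cl, ,
                       drop = FALSE]) / total_rep
  })
  per_class <- matrix(per_class, ncol = length(classes),
                      dimnames = list(table$samples, paste0("frac_", classes)))
  out <- data.frame(sample = table$samples, per_class,
                    repeat_fraction_of_all = total_rep / colSums(table$counts),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Inter-patient variation table for one feature
#'
#' Per-sample normalized values for a single feature together with the
#' across-sample median (the horizontal reference line of an inter-patient
#' variation plot).
#'
#' @param norm normalized matrix (log2 or linear normalized counts) with
#'   feature IDs as row names.
#' @param feature feature ID.
#' @return A list with `values` (data.frame sample, value) and
#'   `cohort_median`.
#' @export
inter_patient_table <- function(norm, feature) {
  if (!feature %in% rownames(norm)) stop("unknown feature: ", feature)
  v <- norm[feature, ]
  list(values = data.frame(sample = colnames(norm), value = unname(v),
                           stringsAsFactors = FALSE),
       cohort_median = stats::median(v))
}
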