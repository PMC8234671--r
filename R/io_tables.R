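#' Parse feature identifiers into gene/repeat annotations
#'
#' Feature identifiers follow the TEtranscripts convention for joint
#' gene + repeat count tables: repeat rows are named as colon-delimited
#' `subfamily:family:class` triples (e.g. `ALR/Alpha:centr:Satellite`),
#' gene rows are plain identifiers without colons.
#'
#' Identifiers with exactly two colons are classified as repeats, identifiers
#' with no colon as genes. Anything else (one colon, three or more colons) is
#' rejected: silently guessing the dialect of an unknown naming scheme is more
#' dangerous than failing loudly.
#'
#' @param ids character vector of feature identifiers.
#' @return A data.frame with columns `feature_id`, `kind` (`"gene"` or
#'   `"repeat"`), `subfamily`, `family`, `repeat_class` (empty strings for
#'   genes).
#' @export
#' @examples
#' parse_feature_ids(c("ENSG00000136997", "ALR/Alpha:centr:Satellite"))
parse_feature_ids <- function(ids) {
  stopifnot(is.character(ids))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate feature ID(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  ncolon <- lengths(gregexpr(":", ids, fixed = TRUE)) -
    (regexpr(":", ids, fixed = TRUE) < 0)
  bad <- which(!(ncolon == 0L | ncolon == 2L))
  if (length(bad)) {
    stop("feature ID(s) with unsupported colon count (expected 0 for genes, ",
         "2 for repeats): ", paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  kind <- ifelse(ncolon == 2L, "repeat", "gene")
  subfamily <- family <- repeat_class <- character(length(ids))
  rep_idx <- kind == "repeat"
  if (any(rep_idx)) {
    parts <- strsplit(ids[rep_idx], ":", fixed = TRUE)
    subfamily[rep_idx] <- vapply(parts, `[`, "", 1L)
    family[rep_idx] <- vapply(parts, `[`, "", 2L)
    repeat_class[rep_idx] <- vapply(parts, `[`, "", 3L)
  }
  data.frame(feature_id = ids, kind = kind, subfamily = subfamily,
             family = family, repeat_class = repeat_class,
             stringsAsFactors = FALSE)
}

new_count_table <- function(counts, features) {
  structure(list(counts = counts, features = features,
                 samples = colnames(counts)),
            class = "rg_count_table")
}

#' Read a joint repeat+gene count table
#'
#' Reads a tab-separated count table in the TEtranscripts output dialect:
#' a header row with the feature-ID column name followed by sample names,
#' then one row per feature with non-negative integer counts. Features are
#' classified as genes or repeats by [parse_feature_ids()].
#'
#' @param path path to a tab-separated count table.
#' @return An object of class `rg_count_table`: a list with
#'   \describe{
#'     \item{counts}{integer matrix, features x samples, with feature IDs as
#'       row names and sample names as column names}
#'     \item{features}{feature annotation data.frame from
#'       [parse_feature_ids()]}
#'     \item{samples}{character vector of sample names}
#'   }
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  nfields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nfields) < 2L) stop("count table has no data rows: ", path)
  bad <- which(nfields != nfields[1L])
  if (length(bad)) {
    stop("malformed row in ", path, ": line ", bad[1L], " has ",
         nfields[bad[1L]], " fields, expected ", nfields[1L])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs at least one sample column")
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample name(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  ids <- df[[1L]]
  features <- parse_feature_ids(ids)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(num)) {
    i <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric count '", raw[i[1L], i[2L]], "' for feature ",
         ids[i[1L]], ", sample ", samples[i[2L]])
  }
  if (any(num < 0)) {
    i <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop("negative count for feature ", ids[i[1L]], ", sample ", samples[i[2L]])
  }
  if (any(num != round(num))) {
    i <- which(num != round(num), arr.ind = TRUE)[1L, ]
    stop("non-integer count for feature ", ids[i[1L]], ", sample ",
         samples[i[2L]])
  }
  counts <- matrix(as.integer(round(num)), nrow = nrow(num),
                   dimnames = list(ids, samples))
  if (!any(features$kind == "gene") || !any(features$kind == "repeat")) {
    stop("count table must contain at least one gene and one repeat feature")
  }
  new_count_table(counts, features)
}

#' Write a count table in the TEtranscripts dialect
#'
#' Inverse of [read_count_table()]; writing then re-reading a canonical table
#' reproduces it byte-identically (tab-separated UTF-8, '.' decimal).
#'
#' @param table an `rg_count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "rg_count_table"))
  df <- data.frame(`gene/TE` = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metadata_numeric_cols <- c("age", "survival_time", "event")

#' Read a sample metadata table
#'
#' Tab-separated with a header; the only required column is `sample`.
#' Recognized optional columns: `gender`, `batch`, `age`, `cytogenetic_risk`
#' (favorable / intermediate / adverse), `subtype`, `survival_time` (days),
#' `event` (0/1), plus any number of 0/1 mutation-flag columns. Missing cells
#' are encoded as `NA` on disk and kept as `NA` (absent, never zero).
#'
#' @param path path to a tab-separated metadata table.
#' @return A data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(df)) stop("metadata must have a 'sample' column")
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample name(s) in metadata: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  for (col in intersect(metadata_numeric_cols, colnames(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_sample_metadata(df)
  df
}

validate_sample_metadata <- function(df) {
  if ("event" %in% colnames(df)) {
    ev <- df$event[!is.na(df$event)]
    if (length(setdiff(ev, c(0, 1)))) stop("event must be 0 or 1")
  }
  has_time <- "survival_time" %in% colnames(df)
  has_event <- "event" %in% colnames(df)
  if (has_time && !has_event) stop("survival_time present without an event column")
  if (has_event && !has_time) stop("event present without a survival_time column")
  if (has_time && has_event) {
    orphan <- which(!is.na(df$event) & is.na(df$survival_time))
    if (length(orphan)) {
      stop("event recorded without survival_time for sample(s): ",
           paste(df$sample[orphan], collapse = ", "))
    }
    orphan2 <- which(!is.na(df$survival_time) & is.na(df$event))
    if (length(orphan2)) {
      stop("survival_time recorded without event for sample(s): ",
           paste(df$sample[orphan2], collapse = ", "))
    }
    if (any(df$survival_time < 0, na.rm = TRUE)) stop("survival_time must be >= 0")
  }
  invisible(df)
}

#' Write a sample metadata table
#'
#' @param meta metadata data.frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Restrict a count table and metadata to their common samples
#'
#' Both inputs are restricted to the intersection of their sample names, in
#' count-table order; dropped samples are reported via a warning.
#'
#' @param table an `rg_count_table`.
#' @param meta metadata data.frame with a `sample` column.
#' @return A list with elements `table` and `meta`, sample-aligned.
#' @export
align_samples <- function(table, meta) {
  stopifnot(inherits(table, "rg_count_table"))
  common <- intersect(table$samples, meta$sample)
  if (!length(common)) stop("count table and metadata share no samples")
  common <- table$samples[table$samples %in% common]
  dropped <- c(setdiff(table$samples, common), setdiff(meta$sample, common))
  if (length(dropped)) {
    warning("dropping sample(s) absent from one input: ",
            paste(dropped, collapse = ", "))
  }
  table$counts <- table$counts[, common, drop = FALSE]
  table$samples <- common
  meta <- meta[match(common, meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  list(table = table, meta = meta)
}

#' @export
print.rg_count_table <- function(x, ...) {
  cat("rg_count_table:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("  genes:  ", sum(x$features$kind == "gene"), "\n")
  cat("  repeats:", sum(x$features$kind == "repeat"),
      sprintf("(%s)", paste(names(sort(table(
        x$features$repeat_class[x$features$kind == "repeat"]), decreasing = TRUE)),
        collapse = ", ")), "\n")
  invisible(x)
}
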