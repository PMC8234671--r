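# Small fixtures built in code at test time.

# Write a count table TSV and read it back through the package reader.
make_count_table <- function(counts, ids, samples = colnames(counts)) {
  rownames(counts) <- NULL
  path <- withr::local_tempfile(fileext = ".cntTable",
                                .local_envir = parent.frame())
  df <- data.frame(`gene/TE` = ids, counts, check.names = FALSE)
  colnames(df) <- c("gene/TE", samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_count_table(path)
}

# A 5-feature (3 genes + 2 repeats), 4-sample table with modest counts.
tiny_table <- function() {
  counts <- matrix(c(10, 20, 30, 40,
                     5, 8, 12, 6,
                     100, 150, 90, 120,
                     2, 0, 4, 1,
                     50, 60, 40, 70),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(NULL, paste0("P", 1:4)))
  ids <- c("ENSG00000000001", "ENSG00000000002", "ENSG00000000003",
           "ALR/Alpha:centr:Satellite", "AluY:Alu:SINE")
  make_count_table(counts, ids)
}

# Survival records as a data.frame.
surv_records <- function(time, event) data.frame(time = time, event = event)
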