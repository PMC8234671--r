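de_fixture <- function(counts) {
  ids <- c(sprintf("ENSG%08d", seq_len(nrow(counts) - 1)), "a:f:SINE")
  make_count_table(counts, ids)
}

test_that("identical constant groups give zero fold change and p near 1", {
  counts <- matrix(50L, nrow = 4, ncol = 8,
                   dimnames = list(NULL, paste0("s", 1:8)))
  tab <- de_fixture(counts)
  res <- nb_wald_test(tab, rep(1, 8), paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(res$log2FoldChange, rep(0, 4))
  expect_true(all(res$pvalue > 0.99))
})

test_that("swapping the groups negates the fold change, p unchanged", {
  set.seed(31)
  counts <- matrix(rnbinom(80, mu = 100, size = 10), nrow = 10,
                   dimnames = list(NULL, paste0("s", 1:8)))
  tab <- de_fixture(counts)
  a <- paste0("s", 1:4); b <- paste0("s", 5:8)
  r1 <- nb_wald_test(tab, rep(1, 8), a, b)
  r2 <- nb_wald_test(tab, rep(1, 8), b, a)
  expect_equal(r1$log2FoldChange, -r2$log2FoldChange, tolerance = 1e-12)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-12)
})

test_that("group preconditions are enforced", {
  counts <- matrix(10L, nrow = 2, ncol = 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  tab <- de_fixture(counts)
  expect_error(nb_wald_test(tab, rep(1, 4), c("s1", "s2"), c("s2", "s3")),
               "disjoint")
  expect_error(nb_wald_test(tab, rep(1, 4), "s1", c("s2", "s3")),
               "at least 2")
})

test_that("BH adjustment matches the hand example and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # monotone: sorting by p sorts padj non-decreasingly
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("significance filter applies strict thresholds and is idempotent", {
  res <- data.frame(feature_id = paste0("f", 1:4), kind = "gene",
                    repeat_class = "",
                    baseMean = c(100, 500, 500, 500),
                    log2FoldChange = c(2, -1.5, 1.0, 2),
                    padj = c(0.01, 0.01, 0.01, 0.05),
                    significant = NA)
  out <- significance_filter(res)
  # baseMean == 100 excluded, |lfc| == 1 excluded, padj == 0.05 excluded
  expect_equal(out$feature_id, "f2")
  expect_equal(colnames(out)[1:2], c("feature_id", "log2FoldChange"))
  expect_equal(significance_filter(out), out)

  set.seed(51)
  for (i in 1:20) {
    n <- 200
    r <- data.frame(feature_id = paste0("f", 1:n), kind = "gene",
                    repeat_class = "",
                    baseMean = runif(n, 0, 300),
                    log2FoldChange = rnorm(n, 0, 1.5),
                    padj = runif(n))
    got <- nrow(significance_filter(r))
    want <- sum(r$baseMean > 100 & abs(r$log2FoldChange) > 1 & r$padj < 0.05)
    expect_equal(got, want)
  }
})

test_that("MA tables carry one labelled row per feature and round-trip", {
  counts <- matrix(rnbinom(60, mu = 200, size = 10), nrow = 6,
                   dimnames = list(NULL, paste0("s", 1:10)))
  tab <- de_fixture(counts)
  res <- nb_wald_test(tab, rep(1, 10), paste0("s", 1:5), paste0("s", 6:10))
  ma <- ma_table(res)
  expect_equal(nrow(ma), 6)
  expect_equal(ma$class_label, c(rep("gene", 5), "SINE"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(format(ma, digits = 6), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read.delim(path)
  expect_equal(back$baseMean, ma$baseMean, tolerance = 1e-5)
  expect_equal(back$log2FoldChange, ma$log2FoldChange, tolerance = 1e-5)

  empty <- ma_table(res[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(colnames(empty), colnames(ma))
})
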