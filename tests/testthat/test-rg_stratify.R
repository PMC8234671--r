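make_norm <- function(rep_vals, gene_vals, sample = "P1") {
  m <- matrix(c(gene_vals, rep_vals), ncol = 1,
              dimnames = list(NULL, sample))
  kinds <- c(rep("gene", length(gene_vals)), rep("repeat", length(rep_vals)))
  rownames(m) <- c(sprintf("ENSG%08d", seq_along(gene_vals)),
                   sprintf("R%d:fam:SINE", seq_along(rep_vals)))
  list(norm = m, kinds = kinds)
}

test_that("R/G ratio is the ratio of kind-wise medians", {
  x <- make_norm(rep_vals = c(1, 2, 3), gene_vals = c(1, 2, 3))
  prof <- rg_profile(x$norm, x$kinds)
  expect_equal(prof$rg_ratio, 1.0)

  # even-length median = mean of the two central values
  x <- make_norm(rep_vals = c(1, 2, 3, 4, 5), gene_vals = c(2, 2, 4, 4))
  prof <- rg_profile(x$norm, x$kinds)
  expect_equal(prof$median_repeat_expr, 3)
  expect_equal(prof$median_gene_expr, 3)
  expect_equal(prof$rg_ratio, 1.0)

  x <- make_norm(rep_vals = 1, gene_vals = 0)
  expect_error(rg_profile(x$norm, x$kinds), "zero")
})

test_that("R/G ratio is invariant to a global positive rescaling", {
  set.seed(5)
  m <- matrix(rlnorm(60, 2, 1), nrow = 12,
              dimnames = list(c(sprintf("ENSG%08d", 1:6),
                                sprintf("R%d:f:LINE", 1:6)),
                              paste0("s", 1:5)))
  kinds <- rep(c("gene", "repeat"), each = 6)
  p1 <- rg_profile(m, kinds)
  p2 <- rg_profile(m * 3.7, kinds)
  expect_equal(p1$rg_ratio, p2$rg_ratio, tolerance = 1e-12)
})

test_that("z-scores have the right normalization and invariances", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(9)
  x <- rnorm(30)
  expect_equal(zscore(2.5 * x + 7), zscore(x), tolerance = 1e-12)
  expect_equal(mean(zscore(x)), 0, tolerance = 1e-12)
  expect_equal(sd(zscore(x)), 1, tolerance = 1e-12)
  expect_error(zscore(c(5, 5)), "zero standard deviation")
  expect_error(zscore(5), "at least 2")
})

test_that("cut_interval splits the range into equal right-closed bins", {
  lab <- cut_interval(c(0, 0.5, 1, 1.5, 2, 2.5, 3), 3)
  expect_equal(as.character(lab),
               c("low", "low", "low", "mid", "mid", "high", "high"))

  # an exact interior edge belongs to the lower bin
  lab <- cut_interval(c(0, 1, 1.5, 3), 3)
  expect_equal(as.character(lab), c("low", "low", "mid", "high"))

  # degenerate range: everything mid
  lab <- cut_interval(rep(2.2, 4), 3)
  expect_equal(as.character(lab), rep("mid", 4))

  expect_error(cut_interval(numeric(0)), "empty")

  # bins cover the range, are disjoint, and have equal width
  set.seed(3)
  for (i in 1:20) {
    x <- runif(50, -10, 10)
    n <- sample(2:6, 1)
    lab <- cut_interval(x, n, labels = paste0("b", 1:n))
    expect_false(anyNA(lab))
    w <- diff(range(x)) / n
    idx <- as.integer(lab)
    lo <- min(x) + (idx - 1) * w
    hi <- min(x) + idx * w
    expect_true(all(x >= lo - 1e-9 & x <= hi + 1e-9))
  }
})

test_that("stratification is affine-invariant and outlier-sensitive", {
  ratios <- c(0.9, 0.92, 0.94, 0.95, 0.97, 3.0)
  prof <- data.frame(sample = paste0("s", 1:6), rg_ratio = ratios)
  out <- stratify_cohort(prof)
  # the single extreme value owns the high stratum
  expect_equal(sum(out$stratum == "high"), 1L)
  expect_equal(as.character(out$stratum[6]), "high")

  # cutting raw ratios gives identical strata to cutting z-scores
  raw <- cut_interval(ratios, 3)
  expect_equal(as.character(out$stratum), as.character(raw))

  # a duplicated sample lands in the same stratum as its twin
  prof2 <- rbind(prof, data.frame(sample = "dup", rg_ratio = ratios[3]))
  out2 <- stratify_cohort(prof2)
  expect_equal(as.character(out2$stratum[7]), as.character(out2$stratum[3]))

  expect_error(stratify_cohort(prof[1:2, ]), "at least 3")
})

test_that("class fractions are read-share arithmetic on raw counts", {
  counts <- matrix(c(200, 40, 30, 9, 1, 20), ncol = 1,
                   dimnames = list(NULL, "P1"))
  ids <- c("ENSG00000000001", "a:f:SINE", "b:f:LINE", "c:f:LTR",
           "d:f:Satellite", "e:f:DNA")
  tab <- make_count_table(counts, ids)
  cf <- class_fractions(tab)
  expect_equal(cf$frac_SINE, 0.40)
  expect_equal(cf$frac_LINE, 0.30)
  expect_equal(cf$frac_LTR, 0.09)
  expect_equal(cf$frac_Satellite, 0.01)
  expect_equal(cf$frac_DNA, 0.20)
  expect_equal(cf$repeat_fraction_of_all, 100 / 300)
  fr <- as.numeric(cf[1, grep("^frac_", colnames(cf))])
  expect_equal(sum(fr), 1, tolerance = 1e-9)

  # single repeat class
  tab1 <- make_count_table(matrix(c(10, 5), ncol = 1,
                                  dimnames = list(NULL, "P1")),
                           c("ENSG00000000001", "a:f:SINE"))
  expect_equal(class_fractions(tab1)$frac_SINE, 1.0)

  # zero repeat reads
  tab0 <- make_count_table(matrix(c(10, 0), ncol = 1,
                                  dimnames = list(NULL, "P1")),
                           c("ENSG00000000001", "a:f:SINE"))
  expect_error(class_fractions(tab0), "zero repeat")
})

test_that("inter-patient tables report per-sample values and the median", {
  m <- matrix(c(1, 2, 9), nrow = 1, dimnames = list("a:f:SINE", paste0("s", 1:3)))
  ipt <- inter_patient_table(m, "a:f:SINE")
  expect_equal(ipt$cohort_median, 2)
  expect_equal(ipt$values$value, c(1, 2, 9))

  m4 <- matrix(c(1, 2, 4, 10), nrow = 1,
               dimnames = list("a:f:SINE", paste0("s", 1:4)))
  expect_equal(inter_patient_table(m4, "a:f:SINE")$cohort_median, 3)

  mc <- matrix(rep(7, 3), nrow = 1, dimnames = list("x:f:LTR", paste0("s", 1:3)))
  expect_equal(inter_patient_table(mc, "x:f:LTR")$cohort_median, 7)

  expect_error(inter_patient_table(m, "nope"), "unknown feature")
})
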