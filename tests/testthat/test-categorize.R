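test_that("transition categories respect the thresholds and boundaries", {
  got <- categorizeTransition(c(1.5, 1.0, 0, -1.0, -1.2))
  expect_identical(as.character(got),
                   c("reduced", "unaltered", "unaltered", "unaltered",
                     "increased"))
  expect_error(categorizeTransition(c(1, NA)), "non-finite")
  expect_error(categorizeTransition(Inf), "non-finite")
})

test_that("severity categories respect the thresholds and boundaries", {
  got <- categorizeSeverity(c(3.0, 2.5, 1.0, 0.9, 0))
  expect_identical(as.character(got),
                   c("strong", "mild", "mild", "none", "none"))
  expect_error(categorizeSeverity(NaN), "non-finite")
})

test_that("severity is monotone in the genotype difference", {
  d <- sort(runif(200, -2, 5))
  ranks <- as.integer(categorizeSeverity(d))
  expect_true(all(diff(ranks) >= 0))
})

test_that("contingency tables tally categories with conserved margins", {
  ten <- factor(rep("unaltered", 10), levels = levels(categorizeTransition(0)))
  names(ten) <- sprintf("g%02d", 1:10)
  tab <- buildContingency(ten, ten)
  expect_equal(unname(tab), rbind(c(0, 10, 0), c(0, 10, 0)))

  expect_error(buildContingency(ten, ten[1:9]), "differ")
  other <- ten
  names(other) <- sprintf("h%02d", 1:10)
  expect_error(buildContingency(ten, other), "differ")

  # planted synthetic truth tallies exactly
  sce <- simulateSpermatogenesis(smallConfig())
  gt <- groundTruth(sce)
  x <- gt$geneTruth[gt$geneTruth$class == "x_silencing", ]
  traj <- normalizeToPreleptotene(gt$trueProfile)
  cats <- suppressWarnings(categorizeGenes(traj))
  tab <- cats$contingency$SP2_SP3
  expect_equal(as.integer(tab["MUT", ]),
               as.integer(table(factor(x$sp2_sp3_category_mut,
                                       levels = colnames(tab)))))
  expect_true(all(rowSums(tab) == nrow(x)))
})

test_that("the exact Fisher r x c test matches independent references", {
  expect_equal(fisherExactRxC(rbind(c(5, 5, 5), c(5, 5, 5))), 1)
  expect_equal(fisherExactRxC(matrix(c(1, 0, 0, 1), 2)), 1.0)
  expect_equal(fisherExactRxC(rbind(c(3, 0, 0), c(0, 3, 0))),
               fisherBruteP(rbind(c(3, 0, 0), c(0, 3, 0))),
               tolerance = 1e-12)
  expect_warning(p <- fisherExactRxC(rbind(c(0, 0, 0), c(1, 2, 3))),
                 "zero margin")
  expect_equal(p, 1)
  expect_error(fisherExactRxC(matrix(1, 1, 3)), "at least 2 x 2")
  expect_error(fisherExactRxC(rbind(c(0.5, 1), c(1, 1))), "integers")

  # 2x2 tables agree with the closed-form hypergeometric test
  set.seed(3)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisherExactRxC(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  # 2x3 tables agree with base R's network-algorithm implementation
  set.seed(4)
  for (i in 1:15) {
    tab <- randomTable23()
    expect_equal(fisherExactRxC(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("the trend test is exact at small n and sane at the extremes", {
  v <- c(1, 1, 2, 2, 3, 3)
  g <- factor(c("none", "none", "mild", "mild", "strong", "strong"),
              levels = c("none", "mild", "strong"))
  r <- severityBaselineTrend(v, g)
  expect_equal(r$statistic, 12)          # every cross-group pair increasing
  expect_equal(r$p.value, 1 / 90)        # 90 distinct assignments, 1 maximal
  expect_equal(r$method, "exact permutation")
  expect_equal(r$groupSummary$median, c(1, 2, 3))

  same <- severityBaselineTrend(rep(2, 10), factor(rep(c("a", "b"), 5)))
  expect_gte(same$p.value, 0.5)

  expect_error(severityBaselineTrend(1:5, factor(rep("a", 5))),
               "two nonempty")
})

test_that("the normal approximation tracks the exact permutation p", {
  set.seed(8)
  v <- round(rnorm(12), 2)
  g <- factor(rep(c("none", "mild", "strong"), each = 4),
              levels = c("none", "mild", "strong"))
  exact <- severityBaselineTrend(v, g)
  approxV <- severityBaselineTrend(c(v, 100), factor(c(as.character(g),
                                                       "strong"), levels(g)))
  expect_equal(exact$method, "exact permutation")
  expect_equal(approxV$method, "normal approximation")
  # null behaviour: exact p for unstructured data is not extreme
  expect_gt(exact$p.value, 0.01)
})

test_that("planted baseline-severity coupling is detected by the trend test", {
  res <- defaultRun()
  expect_lt(res$categories$trend$p.value, 0.01)
})

test_that("pseudobulk correlations behave like Pearson correlations", {
  lc <- cbind(c(1, 0, 2), c(1, 0, 2), c(0, 1, 2), c(0, 1, 2))
  sce <- toySCE(matrix(1L, 3, 4), genotype = rep("WT", 4),
                stage = c("A", "A2", "B", "B2"))
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <- lc
  cm <- pseudobulkCorrelation(sce)
  expect_equal(cm["A.WT", "A2.WT"], 1)                # duplicated profile
  expect_equal(dim(cm), c(4L, 4L))
  expect_equal(cm, t(cm), tolerance = 1e-12)
  expect_true(all(diag(cm) == 1))

  # orthogonal two-gene profiles correlate at -1
  lc2 <- cbind(c(1, 0), c(0, 1))
  sce2 <- toySCE(matrix(1L, 2, 2), genotype = c("WT", "WT"),
                 stage = c("A", "B"))
  SummarizedExperiment::assay(sce2, "logcounts", withDimnames = FALSE) <- lc2
  expect_equal(pseudobulkCorrelation(sce2)["A.WT", "B.WT"], -1)

  # zero-variance group yields NA with a warning
  lc3 <- cbind(c(1, 1), c(0, 1))
  sce3 <- toySCE(matrix(1L, 2, 2), genotype = c("WT", "WT"),
                 stage = c("A", "B"))
  SummarizedExperiment::assay(sce3, "logcounts", withDimnames = FALSE) <- lc3
  expect_warning(cm3 <- pseudobulkCorrelation(sce3), "zero-variance")
  expect_true(is.na(cm3["A.WT", "B.WT"]))
})

test_that("the documented published table is a valid worked input", {
  # genotype x category counts at the pachytene transition, used here as a
  # fixed worked input for the exact test
  tab <- rbind(WT = c(4, 43, 185), MUT = c(74, 134, 24))
  p <- fisherExactRxC(tab)
  expect_lt(p, 1e-30)
  expect_equal(p, fisherBruteP(tab), tolerance = 1e-9)
  expect_true(all(rowSums(tab) == 232))
})
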