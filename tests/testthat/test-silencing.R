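test_that("the X:autosome ratio follows its definition", {
  # identical expression everywhere -> ratio 1
  lcEqual <- matrix(0.7, 4, 3)
  sce <- toySCE(matrix(1L, 4, 3), chromosome = c("X", "X", "9", "9"))
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <- lcEqual
  expect_equal(as.numeric(xAutosomeRatio(sce)), rep(1, 3))

  # X {0.5, 0.5} vs chr9 {1, 1} -> 0.5
  lc <- matrix(c(0.5, 0.5, 1, 1), 4, 1)
  sce1 <- toySCE(matrix(1L, 4, 1), chromosome = c("X", "X", "9", "9"))
  SummarizedExperiment::assay(sce1, "logcounts", withDimnames = FALSE) <- lc
  expect_equal(as.numeric(xAutosomeRatio(sce1)), 0.5)

  # undetected genes count as zeros in the chromosome means
  lc2 <- matrix(c(0.5, 0, 1, 1), 4, 1)
  sce2 <- toySCE(matrix(1L, 4, 1), chromosome = c("X", "X", "9", "9"))
  SummarizedExperiment::assay(sce2, "logcounts", withDimnames = FALSE) <- lc2
  expect_equal(as.numeric(xAutosomeRatio(sce2)), 0.25)
})

test_that("zero denominators give missing ratios with a warning, not failure", {
  lc <- matrix(c(0.5, 0.5, 0, 0,
                 0.5, 0.5, 1, 1), 4, 2)
  sce <- toySCE(matrix(1L, 4, 2), chromosome = c("X", "X", "9", "9"))
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <- lc
  expect_warning(r <- xAutosomeRatio(sce), "undefined")
  expect_true(is.na(r[1]) && r[2] == 0.5)
  expect_equal(attr(r, "nUndefined"), 1L)
})

test_that("the denominator can be chromosome 9 or all autosomes", {
  lc <- matrix(c(2, 1, 3), 3, 1)
  sce <- toySCE(matrix(1L, 3, 1), chromosome = c("X", "9", "5"))
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <- lc
  expect_equal(as.numeric(xAutosomeRatio(sce, denominator = "chr9")), 2)
  expect_equal(as.numeric(xAutosomeRatio(sce, denominator = "all_autosomes")), 1)
})

test_that("wilcoxon comparison matches exact enumeration and handles ties", {
  expect_equal(compareRatioDistributions(c(1, 2), c(3, 4))$p.value, 1 / 3)
  expect_equal(compareRatioDistributions(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(compareRatioDistributions(numeric(0), 1), "nonempty")
  expect_error(compareRatioDistributions(NA_real_, c(1, 2)), "nonempty")

  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    expect_equal(compareRatioDistributions(a, b)$p.value, wilcoxEnumP(a, b),
                 tolerance = 1e-12)
  }
})

test_that("group means are plain averages, order-invariant, and guarded", {
  counts <- matrix(1L, 2, 4)
  sce <- toySCE(counts,
                genotype = factor(c("WT", "WT", "MUT", "MUT"),
                                  levels = c("WT", "MUT")),
                stage = factor(c("PL", "PL", "PL", "PL"),
                               levels = c("PL", "SP1")))
  lc <- matrix(c(1, 0, 3, 0, 2, 5, 4, 5), 2, 4)
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <- lc
  expect_error(stageGenotypeMeans(sce), "SP1")   # empty groups listed

  SummarizedExperiment::colData(sce)$stage <-
    factor(c("PL", "SP1", "PL", "SP1"), levels = c("PL", "SP1"))
  prof <- stageGenotypeMeans(sce)
  expect_equal(prof$mean[prof$gene == "g01" & prof$stage == "PL" &
                           prof$genotype == "WT"], 1)
  expect_equal(prof$mean[prof$gene == "g02" & prof$stage == "SP1" &
                           prof$genotype == "MUT"], 5)
  expect_true(all(prof$n == 1))

  perm <- c(3, 1, 4, 2)
  prof2 <- stageGenotypeMeans(sce[, perm])
  expect_equal(prof2, prof)
})

test_that("informative genes need reads in every stage x genotype group", {
  # 8 X genes; 3 are planted undetectable in one group each
  counts <- matrix(5L, 9, 8)
  counts[2, 1:2] <- 0L          # zero in (PL, WT)
  counts[5, 7:8] <- 0L          # zero in (SP1, MUT)
  counts[8, 3:4] <- 0L          # zero in (SP1, WT)
  counts[9, 5] <- 0L            # still detected in the (PL, MUT) group
  sce <- toySCE(counts, chromosome = c(rep("X", 8), "X"),
                genotype = rep(c("WT", "MUT"), each = 4),
                stage = rep(c("PL", "PL", "SP1", "SP1"), 2))
  got <- selectInformativeGenes(sce, "X")
  expect_identical(got, c("g01", "g03", "g04", "g06", "g07", "g09"))
  expect_error(selectInformativeGenes(sce, "7"), "absent")
})

test_that("a gene with exactly one read per group is informative", {
  counts <- matrix(0L, 2, 4)
  counts[1, ] <- 1L
  counts[2, ] <- 5L
  sce <- toySCE(counts, chromosome = c("X", "X"),
                genotype = c("WT", "WT", "MUT", "MUT"),
                stage = rep(c("PL", "SP1"), 2))
  expect_identical(selectInformativeGenes(sce, "X"), c("g01", "g02"))
})

test_that("pre-leptotene normalization pins PL at zero and subtracts logs", {
  prof <- expand.grid(gene = c("a", "b"), stage = c("PL", "SP1", "SP3"),
                      genotype = c("WT", "MUT"), stringsAsFactors = FALSE)
  prof$mean <- c(2.0, 1.0, 1.5, 0.8, 0.5, 0.4,     # WT: PL PL SP1 SP1 SP3 SP3
                 2.0, 1.0, 1.8, 1.1, 1.9, 1.2)     # MUT
  prof$n <- 10
  attr(prof, "stages") <- c("PL", "SP1", "SP3")
  attr(prof, "genotypes") <- c("WT", "MUT")
  tr <- normalizeToPreleptotene(prof)
  expect_true(all(tr$values$value_PL == 0))
  expect_equal(tr$values$value_SP3[tr$values$gene == "a" &
                                     tr$values$genotype == "WT"], -1.5)
  # genotype difference is mutant minus wild-type
  expect_equal(tr$diffs$diff_SP3[tr$diffs$gene == "a"], -0.1 - (-1.5))
  # telescoping: deltas sum to the final value
  sums <- tr$deltas$delta_PL_SP1 + tr$deltas$delta_SP1_SP3
  expect_equal(sums, tr$values$value_SP3)

  expect_error(normalizeToPreleptotene(prof[prof$stage != "PL", ]),
               "missing")
})

test_that("flat identical trajectories give zero deltas and differences", {
  prof <- expand.grid(gene = "a", stage = c("PL", "SP1", "SP2"),
                      genotype = c("WT", "MUT"), stringsAsFactors = FALSE)
  prof$mean <- 1.3
  prof$n <- 5
  attr(prof, "stages") <- c("PL", "SP1", "SP2")
  attr(prof, "genotypes") <- c("WT", "MUT")
  tr <- normalizeToPreleptotene(prof)
  expect_true(all(tr$deltas$delta_PL_SP1 == 0) &&
                all(tr$deltas$delta_SP1_SP2 == 0))
  expect_true(all(tr$diffs$diff_SP2 == 0))
})

test_that("telescoping holds on estimated trajectories", {
  res <- defaultRun()
  tr <- res$trajectory
  last <- paste0("value_", "SP3")
  sums <- rowSums(tr$deltas[, grep("^delta_", colnames(tr$deltas))])
  expect_equal(sums, tr$values[[last]], tolerance = 1e-12)
})

test_that("wild-type median ratio declines across stages on simulated data", {
  res <- defaultRun()
  cd <- SummarizedExperiment::colData(res$sce)
  wt <- cd$genotype == "WT"
  med <- tapply(res$ratios[wt], as.character(cd$stage[wt]), median,
                na.rm = TRUE)[c("PL", "SP1", "SP2", "SP3")]
  expect_true(all(diff(med) < 0))
})
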