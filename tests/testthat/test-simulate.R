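test_that("identical configurations give bit-identical datasets", {
  cfg <- smallConfig(seed = 7)
  s1 <- simulateSpermatogenesis(cfg)
  s2 <- simulateSpermatogenesis(cfg)
  expect_identical(SummarizedExperiment::assay(s1, "counts"),
                   SummarizedExperiment::assay(s2, "counts"))
  expect_identical(groundTruth(s1), groundTruth(s2))
  s3 <- simulateSpermatogenesis(smallConfig(seed = 8))
  expect_false(identical(SummarizedExperiment::assay(s1, "counts"),
                         SummarizedExperiment::assay(s3, "counts")))
})

test_that("degenerate or infeasible configurations are rejected", {
  expect_error(SimulationConfig(effectMargin = 0), "effectMargin")
  expect_error(SimulationConfig(nXGenes = 0), "positive")
  expect_error(SimulationConfig(stages = c("SP1", "PL")), "PL")
  expect_error(SimulationConfig(nXGenes = 4,
                                xSeverity = c("none", "mild")), "entry per")
  # reduced silencing at SP2->SP3 cannot coexist with "no defect" severity
  expect_error(simulateSpermatogenesis(
    smallConfig(nXGenes = 4, xSeverity = rep("none", 4),
                xTransitionCategory = rep("reduced", 4))),
    "not realizable")
})

test_that("planted categories clear their thresholds by the margin", {
  cfg <- smallConfig(seed = 2, nXGenes = 12,
                     xSeverity = rep("strong", 12),
                     xTransitionCategory = rep("reduced", 12),
                     effectMargin = 0.5)
  gt <- groundTruth(simulateSpermatogenesis(cfg))
  tp <- gt$trueProfile
  mut <- tp[tp$genotype == "MUT", ]
  d3 <- mut$mean[mut$stage == "SP3"] - mut$mean[mut$stage == "SP2"]
  expect_true(all(d3 >= 1.5))           # threshold 1 + margin 0.5
  diff <- tp$mean[tp$stage == "SP3" & tp$genotype == "MUT"] -
    tp$mean[tp$stage == "SP3" & tp$genotype == "WT"]
  expect_true(all(diff >= 3.0))         # threshold 2.5 + margin 0.5
})

test_that("categorizing the true trajectories reproduces the planted truth", {
  sce <- simulateSpermatogenesis(smallConfig())
  gt <- groundTruth(sce)
  x <- gt$geneTruth[gt$geneTruth$class == "x_silencing", ]
  traj <- normalizeToPreleptotene(gt$trueProfile)
  cats <- suppressWarnings(categorizeGenes(traj))
  tr <- cats$transitions
  sub <- tr[tr$transition == "SP2_SP3" & tr$genotype == "MUT", ]
  expect_identical(
    as.character(sub$category[match(x$gene_id, sub$gene)]),
    x$sp2_sp3_category_mut)
  expect_identical(
    as.character(cats$severity$severity[match(x$gene_id,
                                              cats$severity$gene)]),
    x$severity)
})

test_that("wild-type X trajectories decline monotonically to SP3", {
  gt <- groundTruth(simulateSpermatogenesis(smallConfig()))
  tp <- gt$trueProfile[gt$trueProfile$genotype == "WT", ]
  wide <- sapply(c("PL", "SP1", "SP2", "SP3"), function(s)
    tp$mean[tp$stage == s][order(tp$gene[tp$stage == s])])
  expect_true(all(diff(t(wide)) < 0))
})

test_that("empirical group means match the planted values", {
  # law-of-large-numbers fidelity at 500 cells per group, for genes whose
  # count-space mean is not vanishingly small
  res <- largeRun()
  sce <- res$sce
  gt <- groundTruth(sce)
  cd <- SummarizedExperiment::colData(sce)
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  tp <- gt$trueProfile
  err <- mapply(function(g, s, gn, tgt) {
    idx <- cd$true_stage == s & cd$genotype == gn
    muCount <- gt$mu[g, paste(s, gn, sep = ".")]
    if (muCount < 1) return(NA_real_)
    mean(lc[g, idx]) - tgt
  }, tp$gene, tp$stage, tp$genotype, tp$mean)
  err <- err[!is.na(err)]
  # group means are noisy at finite n (se ~ 0.03 at 500 cells), so the 0.1
  # bound is checked in aggregate: nearly all means inside it, tails bounded,
  # and no systematic bias
  expect_gte(mean(abs(err) <= 0.1), 0.99)
  expect_lt(max(abs(err)), 0.2)
  expect_lt(abs(mean(err)), 0.03)
  expect_lt(mean(abs(err)), 0.05)
})

test_that("stage markers peak in their own stage", {
  sce <- smallDataset()
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  cd <- SummarizedExperiment::colData(sce)
  ms <- defaultMarkerSet()
  own <- c(Stra8 = "PL", Rec8 = "PL", Gm960 = "SP1", Prdm9 = "SP1",
           Dazl = "SP2", Sycp1 = "SP2", Id4 = "SP3", Shcbp1l = "SP3",
           Piwil1 = "SP3")
  for (mk in names(own)) {
    means <- tapply(lc[mk, ], cd$true_stage, mean)[ms@stages]
    expect_identical(names(which.max(means)), unname(own[mk]),
                     label = paste("peak stage of", mk))
    expect_true(all(means[own[mk]] > means[setdiff(ms@stages, own[mk])]))
  }
})

test_that("contaminant populations are optional and off by default", {
  sce <- simulateSpermatogenesis(smallConfig())
  expect_false(any(c("SG", "SOM") %in%
                     SummarizedExperiment::colData(sce)$true_stage))
  scec <- simulateSpermatogenesis(smallConfig(includeContaminants = TRUE))
  expect_setequal(unique(SummarizedExperiment::colData(scec)$true_stage),
                  c("PL", "SP1", "SP2", "SP3", "SG", "SOM"))
})

test_that("injected low-quality cells violate exactly one rule each", {
  sce <- simulateSpermatogenesis(smallConfig())
  thr <- QCThresholds(minGenes = 100, minUMIs = 120, maxMitoFraction = 0.05)

  expect_identical(injectLowQualityCells(sce, 0, 0, 0, thr), sce)

  bad <- injectLowQualityCells(sce, nLowGene = 2, nLowUMI = 2, nHighMito = 3,
                               thresholds = thr, seed = 4)
  expect_equal(ncol(bad), ncol(sce) + 7)
  counts <- SummarizedExperiment::assay(bad, "counts")
  cd <- SummarizedExperiment::colData(bad)
  mito <- SummarizedExperiment::rowData(bad)$mito
  planted <- which(!is.na(cd$planted_bad))
  expect_length(planted, 7)

  for (i in planted) {
    v <- counts[, i]
    nGenes <- sum(v > 0)
    nUMIs <- sum(v)
    mitoFrac <- sum(v[mito]) / nUMIs
    viol <- c(low_gene = nGenes < 100, low_umi = nUMIs < 120,
              high_mito = mitoFrac > 0.05)
    expect_identical(names(which(viol)), cd$planted_bad[i])
  }
  expect_equal(sum(cd$planted_bad == "high_mito", na.rm = TRUE), 3)
  lowg <- counts[, cd$planted_bad %in% "low_gene", drop = FALSE]
  expect_true(all(Matrix::colSums(lowg > 0) <= 99))
})

test_that("planting mito violations requires mitochondrial genes", {
  sce <- simulateSpermatogenesis(smallConfig())
  noMito <- sce[!SummarizedExperiment::rowData(sce)$mito, ]
  expect_error(injectLowQualityCells(noMito, nHighMito = 1,
                                     thresholds = QCThresholds(100, 120)),
               "no mitochondrial genes")
})
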