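# Synthetic spermatogenesis generator.
#
# X-gene silencing is planted in the units the pipeline estimates (mean
# log1p-normalized expression per stage x genotype group). The count model is
# NB(mu, size = 1/dispersion) with a per-cell lognormal depth factor; for each
# group the generator numerically inverts E[log1p(kappa * x)] (kappa = scale /
# expected library size) so that the expected observable value of every
# planted gene equals its target. Categories derived from the planted targets
# are therefore exactly the thresholded classification of the truth.

# E[log1p(kappa * x)] for x ~ NB(mu, size), one value per mu.
.elog1p <- function(mu, size, kappa) {
  vapply(mu, function(m) {
    top <- stats::qnbinom(1e-11, mu = m, size = size, lower.tail = FALSE) + 5L
    k <- 0:top
    sum(stats::dnbinom(k, mu = m, size = size) * log1p(kappa * k))
  }, numeric(1))
}

# Invert targets (log1p units) to count-space means for a given kappa.
.invertObservable <- function(targets, kappa, size) {
  muMax <- 2 * (exp(max(targets) + 0.5) - 1) / kappa + 1
  grid <- exp(seq(log(1e-5), log(muMax), length.out = 260))
  e <- .elog1p(grid, size, kappa)
  # e is strictly increasing in mu; interpolate log-mu against it
  exp(stats::approx(e, log(grid), xout = targets, rule = 2)$y)
}

# Wild-type cumulative silencing fractions across K stages (0 at PL, 1 at the
# last stage); the four-stage default front-loads little and ends steep.
.wtDeclineFractions <- function(K) {
  if (K == 4L) return(c(0, 0.2, 7 / 15, 1))
  ((seq_len(K) - 1) / (K - 1))^1.4
}

.CATEGORY_LEVELS <- c("reduced", "unaltered", "increased")
.SEVERITY_LEVELS <- c("none", "mild", "strong")

# Interval of admissible SP2->SP3 deltas for a (category, severity) pair.
# d3w: wild-type delta at the final transition; msp2: mutant level at the
# second-to-last stage; all in log1p units.
.d3Interval <- function(cat, sev, m, d3w, msp2, thr, mutFloor = 0.05) {
  catIv <- switch(cat,
    reduced   = c(thr@transitionHi + m, Inf),
    unaltered = c(thr@transitionLo + m, thr@transitionHi - m),
    increased = c(-Inf, thr@transitionLo - m))
  sevIv <- switch(sev,
    none   = c(-Inf, thr@severityMild - m),
    mild   = c(thr@severityMild + m, thr@severityStrong - m),
    strong = c(thr@severityStrong + m, Inf))
  lo <- max(catIv[1], d3w + sevIv[1], mutFloor - msp2)
  hi <- min(catIv[2], d3w + sevIv[2])
  c(lo, hi)
}

# Plant per-gene baselines and trajectories for the X silencing genes.
.plantXTrajectories <- function(config) {
  K <- length(config@stages)
  m <- config@effectMargin
  w <- .wtDeclineFractions(K)
  thr <- CategoryThresholds()
  n <- config@nXGenes
  sev <- config@xSeverity
  cat23 <- config@xTransitionCategory

  B <- .withSeed(.substreamSeed(config@seed, 0L, 2L),
                 config@xBaselineLog[sev] +
                   stats::rnorm(n, 0, config@xBaselineJitter))
  B <- unname(B)

  D <- d3 <- numeric(n)
  for (g in seq_len(n)) {
    b <- B[g]
    ok <- FALSE
    for (try in 0:30) {          # raise an infeasibly low baseline stepwise
      bb <- b + 0.05 * try
      Dg <- min(config@wtSilencingDepth, bb - config@wtFloor)
      if (Dg <= 0.2) next
      d3w <- -(w[K] - w[K - 1]) * Dg
      msp2 <- bb - w[K - 1] * Dg
      iv <- .d3Interval(cat23[g], sev[g], m, d3w, msp2, thr)
      if (iv[1] <= iv[2]) {
        pref <- d3w + config@severityDiffTargets[[sev[g]]]
        d3[g] <- min(max(pref, iv[1]), iv[2])
        D[g] <- Dg
        B[g] <- bb
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("planted pair (", cat23[g], ", ", sev[g], ") for X gene ", g,
           " is not realizable: no trajectory keeps all expression means ",
           "positive while clearing the thresholds by ", m, " log-units",
           call. = FALSE)
  }

  # target observable levels, genes x stages x genotypes
  M <- array(NA_real_, dim = c(n, K, 2),
             dimnames = list(NULL, config@stages, config@genotypes))
  for (s in seq_len(K)) M[, s, 1] <- B - w[s] * D
  M[, , 2] <- M[, , 1]
  M[, K, 2] <- M[, K - 1, 1] + d3

  # planted categories must be exactly the thresholded truth
  stopifnot(all(as.character(categorizeTransition(M[, K, 2] - M[, K - 1, 2],
                                                  thr)) == cat23),
            all(as.character(categorizeSeverity(M[, K, 2] - M[, K, 1],
                                                thr)) == sev))
  list(B = B, D = D, d3 = d3, M = M)
}

# Marker panel: symbol, chromosome, and a per-stage log-fold exponent profile
# (multiplier = markerFold^exponent). Profiles are keyed by stage position so
# renamed stage vocabularies still work; the default four-stage layout gives
# Stra8 (meiotic entry), Gm960 (leptonema), Dazl (ramp peaking at zygonema,
# falling at pachynema), Id4 and Shcbp1l (pachynema).
.markerPanel <- function(config) {
  K <- length(config@stages)
  stopifnot(K >= 3L)
  mk <- list(
    Stra8   = list(chrom = "6",  p = c(1, -0.5, rep(-1, K - 2))),
    Rec8    = list(chrom = "14", p = c(1, 0, rep(-1, K - 2))),
    Gm960   = list(chrom = "X",  p = c(-1, 1, rep(-1, K - 2))),
    Prdm9   = list(chrom = "17", p = c(-1, 1, rep(0, K - 3), -1)),
    Dazl    = list(chrom = "17", p = c(0.3, 0.8, rep(1, K - 3), -1)),
    Sycp1   = list(chrom = "3",  p = c(-1, -0.3, rep(1, K - 3), 0.3)),
    Id4     = list(chrom = "13", p = c(-0.5, -0.5, rep(0, K - 3), 1)),
    Shcbp1l = list(chrom = "1",  p = c(-0.5, -0.5, rep(0, K - 3), 1)),
    Piwil1  = list(chrom = "5",  p = c(-1, -1, rep(-0.3, K - 3), 1)))
  if (config@includeContaminants) {
    mk$Sall4  <- list(chrom = "2",  p = rep(0, K), sg = 1,  som = -1)
    mk$Dmrt1  <- list(chrom = "19", p = rep(0, K), sg = 1,  som = -1)
    mk$Col1a2 <- list(chrom = "6",  p = rep(0, K), sg = -1, som = 1)
    mk$Vim    <- list(chrom = "2",  p = rep(0, K), sg = -1, som = 1)
  }
  mk
}

#' Simulate a spermatogenesis scRNA-seq dataset with planted silencing truth
#'
#' Generates a two-genotype, staged spermatogenesis dataset: overdispersed
#' (negative-binomial) UMI counts with per-cell depth variation, stage marker
#' genes, stage-stable autosomal and mitochondrial genes, and X-linked genes
#' whose silencing trajectories -- monotone decline in the wild type,
#' incomplete silencing at the pachytene stage in the mutant -- are planted so
#' that every gene's transition and severity category is known and recoverable
#' by the downstream pipeline. Identical configurations produce bit-identical
#' datasets.
#'
#' @param config a [SimulationConfig()].
#' @return A \code{SingleCellExperiment} with a \code{counts} assay, gene
#'   annotation in \code{rowData} (\code{gene_id}, \code{gene_name},
#'   \code{chromosome}, \code{mito}, \code{class}), per-cell \code{genotype}
#'   and \code{true_stage} in \code{colData}, and the planted
#'   [groundTruth()] in \code{metadata}.
#' @examples
#' sce <- simulateSpermatogenesis(SimulationConfig(seed = 7,
#'   nCellsPerGroup = 40, nXGenes = 24, nChr9Genes = 20, nOtherGenes = 80))
#' sce
#' @export
simulateSpermatogenesis <- function(config = SimulationConfig()) {
  methods::validObject(config)
  stages <- config@stages
  genos <- config@genotypes
  K <- length(stages)
  size <- 1 / config@dispersion

  # --- gene panel ------------------------------------------------------
  markers <- .markerPanel(config)
  otherChroms <- setdiff(as.character(1:19), "9")
  genes <- data.frame(
    gene_id = c(sprintf("Xg%03d", seq_len(config@nXGenes)),
                sprintf("C9g%03d", seq_len(config@nChr9Genes)),
                sprintf("Ag%04d", seq_len(config@nOtherGenes)),
                sprintf("mt-g%02d", seq_len(config@nMitoGenes)),
                names(markers)),
    chromosome = c(rep("X", config@nXGenes),
                   rep("9", config@nChr9Genes),
                   rep(otherChroms,
                       length.out = config@nOtherGenes),
                   rep("MT", config@nMitoGenes),
                   vapply(markers, `[[`, "", "chrom")),
    class = c(rep("x_silencing", config@nXGenes),
              rep("chr9", config@nChr9Genes),
              rep("autosomal", config@nOtherGenes),
              rep("mito", config@nMitoGenes),
              rep("marker", length(markers))),
    stringsAsFactors = FALSE)
  genes$gene_name <- genes$gene_id
  genes$mito <- genes$chromosome == "MT"
  nGenes <- nrow(genes)

  # --- groups ----------------------------------------------------------
  grpStage <- rep(stages, times = length(genos))
  grpGeno <- rep(genos, each = K)
  if (config@includeContaminants) {
    grpStage <- c(grpStage, rep(c("SG", "SOM"), times = length(genos)))
    grpGeno <- c(grpGeno, rep(genos, each = 2))
  }
  nGrp <- length(grpStage)
  grpName <- paste(grpStage, grpGeno, sep = ".")

  # --- count-space means -----------------------------------------------
  bgIdx <- which(genes$class %in% c("chr9", "autosomal"))
  mitoIdx <- which(genes$class == "mito")
  mkIdx <- which(genes$class == "marker")
  xIdx <- which(genes$class == "x_silencing")

  bgMu <- .withSeed(.substreamSeed(config@seed, 0L, 1L),
    config@baselineMean * exp(stats::rnorm(length(bgIdx), 0,
                                           config@baselineLogSigma)))
  # relative abundances of the mitochondrial genes; absolute level is set per
  # group so the mito pool holds a constant fraction of the library
  mitoW <- .withSeed(.substreamSeed(config@seed, 0L, 3L),
    exp(stats::rnorm(length(mitoIdx), 0, 0.2)))
  mitoW <- mitoW / sum(mitoW)
  fm <- config@mitoFraction

  mu <- matrix(0, nGenes, nGrp, dimnames = list(genes$gene_id, grpName))
  mu[bgIdx, ] <- bgMu
  for (i in seq_along(markers)) {
    mk <- markers[[i]]
    expo <- vapply(seq_len(nGrp), function(g) {
      st <- grpStage[g]
      if (st == "SG") mk$sg %||% 0
      else if (st == "SOM") mk$som %||% 0
      else mk$p[match(st, stages)]
    }, numeric(1))
    mu[mkIdx[i], ] <- config@markerBaselineMean * config@markerFold^expo
  }

  plant <- .plantXTrajectories(config)
  stageGrp <- match(grpStage, stages)            # NA for contaminant groups
  genoGrp <- match(grpGeno, genos)
  # initialize X means from targets at a provisional library size
  S0 <- colSums(mu)[1] + sum(expm1(plant$B))
  for (g in seq_len(nGrp)) {
    tgt <- if (is.na(stageGrp[g])) plant$B else plant$M[, stageGrp[g], genoGrp[g]]
    mu[xIdx, g] <- expm1(tgt) * S0 / config@scaleFactor
  }
  # iterate: library size -> kappa -> inversion of planted targets; the
  # mitochondrial pool tracks the cell's nuclear RNA content (constant mito
  # fraction), so X silencing does not inflate the mito share of late stages
  nonMitoS <- colSums(mu[-mitoIdx, , drop = FALSE])
  mu[mitoIdx, ] <- outer(mitoW, fm / (1 - fm) * nonMitoS)
  for (iter in 1:40) {
    S <- colSums(mu)
    for (g in seq_len(nGrp)) {
      kappa <- config@scaleFactor / S[g]
      tgt <- if (is.na(stageGrp[g])) plant$B
             else plant$M[, stageGrp[g], genoGrp[g]]
      mu[xIdx, g] <- .invertObservable(tgt, kappa, size)
    }
    nonMitoS <- colSums(mu[-mitoIdx, , drop = FALSE])
    mu[mitoIdx, ] <- outer(mitoW, fm / (1 - fm) * nonMitoS)
    if (max(abs(colSums(mu) - S) / S) < 1e-5) break
  }
  if (any(mu[xIdx, ] <= 0))
    stop("planted trajectory implies a nonpositive expression mean",
         call. = FALSE)

  # --- draw counts ------------------------------------------------------
  n <- config@nCellsPerGroup
  counts <- matrix(0L, nGenes, nGrp * n)
  sig <- config@depthLognormalSigma
  for (g in seq_len(nGrp)) {
    depth <- .withSeed(.substreamSeed(config@seed, g, 0L),
      exp(stats::rnorm(n, -sig^2 / 2, sig)))
    cols <- (g - 1L) * n + seq_len(n)
    for (j in seq_len(nGenes)) {
      counts[j, cols] <- .withSeed(.substreamSeed(config@seed, g, j),
        stats::rnbinom(n, mu = depth * mu[j, g], size = size))
    }
  }
  barcodes <- sprintf("BC%06d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes$gene_id, barcodes)

  cellTruth <- data.frame(barcode = barcodes,
                          genotype = rep(grpGeno, each = n),
                          true_stage = rep(grpStage, each = n),
                          stringsAsFactors = FALSE)

  # --- truth tables -----------------------------------------------------
  geneTruth <- data.frame(gene_id = genes$gene_id, class = genes$class,
                          chromosome = genes$chromosome,
                          severity = NA_character_,
                          sp2_sp3_category_mut = NA_character_,
                          baseline_log = NA_real_, stringsAsFactors = FALSE)
  geneTruth$severity[xIdx] <- config@xSeverity
  geneTruth$sp2_sp3_category_mut[xIdx] <- config@xTransitionCategory
  geneTruth$baseline_log[xIdx] <- plant$B

  trueProfile <- expand.grid(gene = genes$gene_id[xIdx], stage = stages,
                             genotype = genos, stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)
  trueProfile$mean <- as.vector(plant$M)
  trueProfile$n <- NA_integer_

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(
      gene_id = genes$gene_id, gene_name = genes$gene_name,
      chromosome = genes$chromosome, mito = genes$mito, class = genes$class,
      row.names = genes$gene_id),
    colData = S4Vectors::DataFrame(
      barcode = barcodes, genotype = cellTruth$genotype,
      true_stage = cellTruth$true_stage, row.names = barcodes))
  S4Vectors::metadata(sce)$groundTruth <- list(
    cellTruth = cellTruth, geneTruth = geneTruth, mu = mu,
    trueProfile = trueProfile, stages = stages, genotypes = genos)
  S4Vectors::metadata(sce)$simulationConfig <- config
  sce
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append low-quality cells that violate one QC rule each
#'
#' Adds synthetic problem cells to a simulated dataset, each violating exactly
#' one of the three quality rules (too few detected genes, too few UMIs, or
#' an excessive mitochondrial fraction), flagged in \code{colData$planted_bad}.
#' Used to exercise [filterCells()].
#'
#' @param sce a \code{SingleCellExperiment} with counts and a logical
#'   \code{mito} column in \code{rowData}.
#' @param nLowGene,nLowUMI,nHighMito number of cells to append per violation.
#' @param thresholds the [QCThresholds()] the violations are planted against.
#' @param seed seed for the gene placement of the planted cells.
#' @return The input object with the planted cells appended;
#'   returned unchanged when all three counts are zero.
#' @export
injectLowQualityCells <- function(sce, nLowGene = 0L, nLowUMI = 0L,
                                  nHighMito = 0L, thresholds = QCThresholds(),
                                  seed = 1L) {
  if (nLowGene == 0L && nLowUMI == 0L && nHighMito == 0L) return(sce)
  counts <- .assayOrStop(sce, "counts")
  mito <- SummarizedExperiment::rowData(sce)$mito
  if (is.null(mito))
    stop("rowData(sce)$mito is required to plant QC violations",
         call. = FALSE)
  if (nHighMito > 0L && !any(mito))
    stop("cannot plant high-mito cells: no mitochondrial genes annotated",
         call. = FALSE)
  nonMito <- which(!mito)
  minG <- thresholds@minGenes
  minU <- thresholds@minUMIs
  maxF <- thresholds@maxMitoFraction

  if (nLowGene > 0L && length(nonMito) < minG - 1L)
    stop("cannot plant low-gene cells: fewer than minGenes-1 non-mito genes",
         call. = FALSE)
  if (nLowUMI > 0L &&
      (minU - 1L < minG || length(nonMito) < minG))
    stop("cannot plant low-UMI cells violating only the UMI rule",
         call. = FALSE)

  newCols <- list()
  labels <- character()
  .withSeed(seed, {
    for (i in seq_len(nLowGene)) {          # minGenes-1 genes, ample UMIs
      v <- numeric(nrow(counts))
      pick <- sample(nonMito, minG - 1L)
      v[pick] <- ceiling(1.5 * minU / max(1L, minG - 1L))
      newCols[[length(newCols) + 1L]] <- v
      labels <- c(labels, "low_gene")
    }
    for (i in seq_len(nLowUMI)) {           # minUMIs-1 UMIs over >= minGenes genes
      v <- numeric(nrow(counts))
      k <- min(length(nonMito), minU - 1L)
      pick <- sample(nonMito, k)
      base <- (minU - 1L) %/% k
      v[pick] <- base
      extra <- (minU - 1L) - base * k
      if (extra > 0L) v[pick[seq_len(extra)]] <- base + 1L
      newCols[[length(newCols) + 1L]] <- v
      labels <- c(labels, "low_umi")
    }
    for (i in seq_len(nHighMito)) {         # mito fraction just above the cap
      v <- numeric(nrow(counts))
      k <- min(length(nonMito), max(minG, 600L))
      pick <- sample(nonMito, k)
      v[pick] <- ceiling(2 * minU / k)
      tot <- sum(v)
      f <- min(0.999, maxF * 1.2 + 0.01)
      mtot <- ceiling(f / (1 - f) * tot)
      mIdx <- which(mito)
      per <- mtot %/% length(mIdx)
      v[mIdx] <- per
      v[mIdx[1L]] <- per + (mtot - per * length(mIdx))
      newCols[[length(newCols) + 1L]] <- v
      labels <- c(labels, "high_mito")
    }
  })

  extra <- methods::as(do.call(cbind, newCols), "CsparseMatrix")
  badBc <- sprintf("BAD_%s_%03d", toupper(labels), seq_along(labels))
  colnames(extra) <- badBc
  rownames(extra) <- rownames(counts)

  cd <- SummarizedExperiment::colData(sce)
  cdNew <- cd[rep(NA_integer_, length(badBc)), , drop = FALSE]
  rownames(cdNew) <- badBc
  if ("barcode" %in% colnames(cdNew)) cdNew$barcode <- badBc
  cdAll <- rbind(cd, cdNew)
  if (!"planted_bad" %in% colnames(cdAll)) cdAll$planted_bad <- NA_character_
  cdAll$planted_bad[seq(nrow(cd) + 1L, nrow(cdAll))] <- labels

  out <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cbind(counts, extra)),
    rowData = SummarizedExperiment::rowData(sce),
    colData = cdAll)
  S4Vectors::metadata(out) <- S4Vectors::metadata(sce)
  out
}
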