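# Silencing statistics: per-cell X:autosome ratios, stage x genotype mean
# profiles, pre-leptotene-normalized trajectories and genotype differences.

#' Per-cell X-to-autosome expression ratio
#'
#' For every cell, the mean log-normalized expression over all annotated
#' genes of the numerator chromosome (zeros included) divided by the same
#' mean over the denominator gene set -- either the chromosome 9 reference
#' set or all autosomes. The ratio tracks meiotic sex chromosome
#' inactivation: it falls as the X is silenced across prophase I.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts} and a
#'   \code{chromosome} column in \code{rowData}.
#' @param numerator numerator chromosome label (default \code{"X"}).
#' @param denominator \code{"chr9"} (default, the reference autosome) or
#'   \code{"all_autosomes"}.
#' @return Named numeric vector of per-cell ratios. Cells whose denominator
#'   mean is zero get \code{NA}; their number is attached as
#'   \code{attr(, "nUndefined")} and reported in a warning rather than
#'   failing the run.
#' @export
xAutosomeRatio <- function(sce, numerator = "X",
                           denominator = c("chr9", "all_autosomes")) {
  denominator <- match.arg(denominator)
  lc <- .assayOrStop(sce, "logcounts")
  chrom <- SummarizedExperiment::rowData(sce)$chromosome
  if (is.null(chrom))
    stop("rowData(sce)$chromosome is required", call. = FALSE)
  denChrom <- if (denominator == "chr9") "9" else as.character(1:19)
  if (numerator %in% denChrom)
    stop("numerator chromosome cannot be part of the denominator",
         call. = FALSE)
  num <- chrom == numerator
  den <- chrom %in% denChrom
  if (!any(num)) stop("no genes on numerator chromosome ", numerator,
                      call. = FALSE)
  if (!any(den)) stop("no genes in the denominator set", call. = FALSE)
  numMean <- Matrix::colMeans(lc[num, , drop = FALSE])
  denMean <- Matrix::colMeans(lc[den, , drop = FALSE])
  ratio <- ifelse(denMean > 0, numMean / denMean, NA_real_)
  names(ratio) <- colnames(sce)
  nUndef <- sum(is.na(ratio))
  if (nUndef > 0)
    warning(nUndef, " cell(s) with zero denominator mean: ratio undefined",
            call. = FALSE)
  attr(ratio, "nUndefined") <- nUndef
  ratio
}

#' Two-sided Wilcoxon rank-sum comparison of ratio distributions
#'
#' Compares two samples (typically per-cell X:autosome ratios of the two
#' genotypes at one stage) with the two-sided Wilcoxon rank-sum
#' (Mann-Whitney) test. The exact null distribution is used when the smaller
#' sample has at most 8 observations and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used.
#' Missing values are dropped first.
#'
#' @param a,b numeric samples; each must be nonempty after removing
#'   \code{NA}s.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) the exact path;
#'   \code{NULL} (default) applies the rule above.
#' @return A list with \code{statistic} (Mann-Whitney W for the first
#'   sample), \code{p.value} and \code{method}.
#' @export
compareRatioDistributions <- function(a, b, exact = NULL) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("both samples must be nonempty after dropping missing values",
         call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- min(length(a), length(b)) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (exact && !ties) "exact" else "normal approximation")
}

#' Mean expression per gene, stage and genotype
#'
#' Averages log-normalized expression over the cells of every
#' (stage, genotype) group, recording group sizes. This per-group profile is
#' the input to pre-leptotene normalization.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts} and
#'   \code{stage} and \code{genotype} columns in \code{colData}.
#' @return A long data.frame with columns \code{gene}, \code{stage},
#'   \code{genotype}, \code{mean}, \code{n}; stage and genotype orders are
#'   kept as attributes.
#' @export
stageGenotypeMeans <- function(sce) {
  lc <- .assayOrStop(sce, "logcounts")
  stage <- .colDataOrStop(sce, "stage", "run assignStages() first")
  geno <- .colDataOrStop(sce, "genotype", "per-cell genotype labels required")
  stages <- if (is.factor(stage)) levels(stage) else unique(stage)
  genos <- if (is.factor(geno)) levels(geno) else unique(geno)
  grid <- expand.grid(stage = stages, genotype = genos,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  empty <- character()
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    idx <- which(stage == grid$stage[i] & geno == grid$genotype[i])
    if (!length(idx)) {
      empty <- c(empty, paste0("(", grid$stage[i], ", ", grid$genotype[i], ")"))
      next
    }
    out[[i]] <- data.frame(gene = rownames(lc), stage = grid$stage[i],
                           genotype = grid$genotype[i],
                           mean = Matrix::rowMeans(lc[, idx, drop = FALSE]),
                           n = length(idx), stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  if (length(empty))
    stop("empty (stage, genotype) group(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  prof <- do.call(rbind, out)
  attr(prof, "stages") <- stages
  attr(prof, "genotypes") <- genos
  prof
}

#' Select informative genes of a chromosome
#'
#' Returns the genes of the requested chromosome that have at least one raw
#' read in at least one cell of \emph{every} (stage, genotype) group -- the
#' eligibility rule for trajectory categorization. Ordering follows the
#' annotation (row) order.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts},
#'   \code{chromosome} in \code{rowData} and \code{stage}/\code{genotype} in
#'   \code{colData}.
#' @param chromosome chromosome label (default \code{"X"}).
#' @return Character vector of informative gene IDs.
#' @export
selectInformativeGenes <- function(sce, chromosome = "X") {
  counts <- .assayOrStop(sce, "counts")
  chrom <- SummarizedExperiment::rowData(sce)$chromosome
  if (is.null(chrom))
    stop("rowData(sce)$chromosome is required", call. = FALSE)
  if (!chromosome %in% chrom)
    stop("chromosome '", chromosome, "' absent from the annotation",
         call. = FALSE)
  stage <- .colDataOrStop(sce, "stage", "run assignStages() first")
  geno <- .colDataOrStop(sce, "genotype", "per-cell genotype labels required")
  onChrom <- which(chrom == chromosome)
  grp <- interaction(stage, geno, drop = TRUE)
  sub <- counts[onChrom, , drop = FALSE]
  detected <- vapply(levels(grp), function(g)
    Matrix::rowSums(sub[, grp == g, drop = FALSE]) > 0,
    logical(length(onChrom)))
  rownames(counts)[onChrom[rowSums(!detected) == 0]]
}

#' Normalize stage profiles to the pre-leptotene baseline
#'
#' Re-expresses each gene's per-stage means relative to its own pre-leptotene
#' level by log-unit subtraction, so every trajectory starts at exactly 0 and
#' later values are log fold-changes versus pre-leptotene (negative =
#' silencing). Also tabulates the per-transition deltas and the per-stage
#' genotype difference (mutant minus wild-type, so failure to silence is
#' positive).
#'
#' @param profile output of [stageGenotypeMeans()] (or the ground-truth
#'   profile of a simulation).
#' @param genes optional gene subset (e.g. from [selectInformativeGenes()]);
#'   default all genes in the profile.
#' @param plStage name of the baseline stage (default first stage of the
#'   profile's stage order).
#' @return A list of three data.frames: \code{values} (gene, genotype, one
#'   \code{value_<stage>} column per stage), \code{deltas} (gene, genotype,
#'   one \code{delta_<from>_<to>} column per transition) and \code{diffs}
#'   (gene, one \code{diff_<stage>} column per stage, second genotype minus
#'   first).
#' @export
normalizeToPreleptotene <- function(profile, genes = NULL, plStage = NULL) {
  stages <- attr(profile, "stages")
  if (is.null(stages)) stages <- unique(profile$stage)
  genos <- attr(profile, "genotypes")
  if (is.null(genos)) genos <- unique(profile$genotype)
  if (length(genos) < 1L) stop("profile has no genotypes", call. = FALSE)
  if (is.null(plStage)) plStage <- stages[1L]
  if (!plStage %in% stages) stop("baseline stage '", plStage,
                                 "' not in the profile", call. = FALSE)
  if (is.null(genes)) genes <- unique(profile$gene)
  sub <- profile[profile$gene %in% genes, , drop = FALSE]

  # wide matrix gene x (stage, genotype)
  val <- lapply(genos, function(gn) {
    m <- sapply(stages, function(s) {
      rows <- sub[sub$stage == s & sub$genotype == gn, ]
      v <- rows$mean[match(genes, rows$gene)]
      v
    })
    m <- matrix(m, nrow = length(genes),
                dimnames = list(genes, stages))
    if (anyNA(m[, plStage]))
      stop("gene(s) missing a ", plStage, " mean: ",
           paste(utils::head(genes[is.na(m[, plStage])], 5), collapse = ", "),
           call. = FALSE)
    m - m[, plStage]
  })
  names(val) <- genos

  values <- do.call(rbind, lapply(genos, function(gn) {
    d <- data.frame(gene = genes, genotype = gn, stringsAsFactors = FALSE)
    for (s in stages) d[[paste0("value_", s)]] <- val[[gn]][, s]
    d
  }))
  deltas <- do.call(rbind, lapply(genos, function(gn) {
    d <- data.frame(gene = genes, genotype = gn, stringsAsFactors = FALSE)
    for (i in seq_len(length(stages) - 1L))
      d[[paste0("delta_", stages[i], "_", stages[i + 1L])]] <-
        val[[gn]][, i + 1L] - val[[gn]][, i]
    d
  }))
  diffs <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (length(genos) >= 2L) {
    for (s in stages)
      diffs[[paste0("diff_", s)]] <- val[[genos[2L]]][, s] - val[[genos[1L]]][, s]
  }
  rownames(values) <- rownames(deltas) <- rownames(diffs) <- NULL
  structure(list(values = values, deltas = deltas, diffs = diffs),
            stages = stages, genotypes = genos, class = "msciTrajectory")
}

#' @export
print.msciTrajectory <- function(x, ...) {
  cat("Pre-leptotene-normalized trajectories:",
      length(unique(x$values$gene)), "genes x",
      length(attr(x, "genotypes")), "genotypes over stages",
      paste(attr(x, "stages"), collapse = " -> "), "\n")
  invisible(x)
}
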