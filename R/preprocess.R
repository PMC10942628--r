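# Cell-level QC and depth normalization.

.perCellQC <- function(counts, mito) {
  nUMIs <- Matrix::colSums(counts)
  nGenes <- Matrix::colSums(counts > 0)
  mitoCounts <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE])
                else numeric(ncol(counts))
  mitoFrac <- ifelse(nUMIs > 0, mitoCounts / nUMIs, 0)
  data.frame(barcode = colnames(counts), n_genes = as.integer(nGenes),
             n_umis = as.integer(nUMIs), mito_fraction = mitoFrac,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter cells on detected genes, UMI count and mitochondrial fraction
#'
#' Applies the three exclusion rules: cells with fewer than
#' \code{minGenes} detected genes, fewer than \code{minUMIs} total counts, or
#' a mitochondrial count fraction above \code{maxMitoFraction} are removed.
#' All rules are strict, so a cell sitting exactly on a boundary (say 500
#' genes, 1000 UMIs, 5.0\% mito under the defaults) is retained. The gene
#' axis is untouched and a per-cell report covering every input cell is
#' attached (see [qcReport()]).
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay and a
#'   logical \code{mito} column in \code{rowData}.
#' @param thresholds a [QCThresholds()] object.
#' @return The filtered \code{SingleCellExperiment}; errors if no cell
#'   survives, which usually indicates thresholds unsuited to the data.
#' @examples
#' sce <- simulateSpermatogenesis(SimulationConfig(seed = 1,
#'   nCellsPerGroup = 20, nXGenes = 12, nChr9Genes = 10, nOtherGenes = 50))
#' filtered <- filterCells(sce, QCThresholds(minGenes = 10, minUMIs = 50))
#' head(qcReport(filtered))
#' @export
filterCells <- function(sce, thresholds = QCThresholds()) {
  methods::validObject(thresholds)
  counts <- .assayOrStop(sce, "counts")
  mito <- SummarizedExperiment::rowData(sce)$mito
  if (is.null(mito))
    stop("rowData(sce)$mito (logical mitochondrial flag) is required",
         call. = FALSE)
  rep <- .perCellQC(counts, mito)
  lowG <- rep$n_genes < thresholds@minGenes
  lowU <- rep$n_umis < thresholds@minUMIs
  hiM <- rep$mito_fraction > thresholds@maxMitoFraction
  rep$kept <- !(lowG | lowU | hiM)
  reasons <- cbind(ifelse(lowG, "low_genes", NA),
                   ifelse(lowU, "low_umis", NA),
                   ifelse(hiM, "high_mito", NA))
  rep$reasons <- apply(reasons, 1, function(r)
    paste(r[!is.na(r)], collapse = ","))
  if (!any(rep$kept))
    stop("all ", nrow(rep), " cells fail the QC thresholds; ",
         "review minGenes/minUMIs/maxMitoFraction against this dataset",
         call. = FALSE)
  out <- sce[, rep$kept]
  S4Vectors::metadata(out)$qcReport <- rep
  out
}

#' Depth-normalize and log-transform counts
#'
#' Per-cell library-size normalization followed by a natural-log transform:
#' \code{value(j, c) = log(1 + scaleFactor * count(j, c) / total(c))}. Zero
#' counts map to zero, so sparsity is preserved, and for every cell the sum
#' of \code{expm1(value)} equals \code{scaleFactor} exactly. This is the
#' standard counts-per-10,000 log1p normalization of droplet scRNA-seq
#' toolkits, and it fixes the log-unit scale on which all downstream
#' trajectory thresholds operate.
#'
#' @param sce a \code{SingleCellExperiment}; every cell must have a positive
#'   total count (run [filterCells()] first).
#' @param scaleFactor target library size after scaling (default 10,000).
#' @return The object with a \code{logcounts} assay added.
#' @export
logNormalizeCounts <- function(sce, scaleFactor = 10000) {
  counts <- .assayOrStop(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(utils::head(colnames(sce)[totals == 0], 5), collapse = ", "),
         " -- run filterCells() first", call. = FALSE)
  m <- methods::as(counts, "CsparseMatrix")
  percell <- rep.int(totals, diff(m@p))
  m@x <- log1p(m@x * scaleFactor / percell)
  SummarizedExperiment::assay(sce, "logcounts") <- m
  S4Vectors::metadata(sce)$scaleFactor <- scaleFactor
  sce
}
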