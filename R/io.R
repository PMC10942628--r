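# 10x-style on-disk dialect:
#   matrix.mtx      MatrixMarket coordinate integer general, 1-based indices
#   features.tsv    header: gene_id, gene_name, chromosome, mito_flag (0/1)
#   barcodes.tsv    one barcode per line, no header
#   cell_metadata.tsv  optional; header: barcode, genotype, [true_]stage
# Indices are converted to R's convention at this boundary only.

#' Read a 10x-style count directory
#'
#' Reads a MatrixMarket triplet count matrix with its features and barcodes
#' sidecars (the dialect written by [write10x()]) and returns a validated
#' \code{SingleCellExperiment}. Counts must be nonnegative integers, gene IDs
#' and barcodes unique, and dimensions consistent; violations raise a format
#' error naming the offending file and record.
#'
#' @param dir directory containing \code{matrix.mtx}, \code{features.tsv} and
#'   \code{barcodes.tsv}, plus optional \code{cell_metadata.tsv}.
#' @return A \code{SingleCellExperiment} with a sparse integer \code{counts}
#'   assay, gene annotation in \code{rowData} and any cell metadata in
#'   \code{colData}.
#' @seealso [write10x()], [loadAnnotation()]
#' @export
read10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  ftr <- file.path(dir, "features.tsv")
  bcf <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, ftr, bcf))
    if (!file.exists(f)) .formatError(f, "required file is missing")

  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) .formatError(mtx, paste(
                  "not a readable MatrixMarket file:", conditionMessage(e))),
                warning = function(w) .formatError(mtx, paste(
                  "malformed MatrixMarket file:", conditionMessage(w))))
  m <- methods::as(m, "CsparseMatrix")
  if (length(m@x) && any(m@x < 0))
    .formatError(mtx, "negative count encountered", field = "value")
  if (length(m@x) && any(m@x != floor(m@x)))
    .formatError(mtx, "non-integer count encountered", field = "value")

  feats <- utils::read.delim(ftr, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("gene_id", "gene_name", "chromosome", "mito_flag")
  miss <- setdiff(need, colnames(feats))
  if (length(miss))
    .formatError(ftr, paste("missing required column(s):",
                            paste(miss, collapse = ", ")),
                 field = miss[1])
  dup <- feats$gene_id[duplicated(feats$gene_id)]
  if (length(dup))
    .formatError(ftr, paste("duplicate gene_id:",
                            paste(unique(dup), collapse = ", ")),
                 field = "gene_id")
  bad <- setdiff(unique(feats$chromosome), .chromVocabulary())
  if (length(bad))
    .formatError(ftr, paste("unknown chromosome label(s):",
                            paste(bad, collapse = ", ")),
                 field = "chromosome")

  barcodes <- readLines(bcf)
  dupB <- barcodes[duplicated(barcodes)]
  if (length(dupB))
    .formatError(bcf, paste("duplicate barcode:",
                            paste(unique(dupB), collapse = ", ")))

  if (nrow(m) != nrow(feats))
    .formatError(mtx, sprintf(
      "matrix has %d rows but features.tsv has %d records",
      nrow(m), nrow(feats)))
  if (ncol(m) != length(barcodes))
    .formatError(mtx, sprintf(
      "matrix has %d columns but barcodes.tsv has %d records",
      ncol(m), length(barcodes)))

  dimnames(m) <- list(feats$gene_id, barcodes)
  rd <- S4Vectors::DataFrame(gene_id = feats$gene_id,
                             gene_name = feats$gene_name,
                             chromosome = feats$chromosome,
                             mito = feats$mito_flag == "1",
                             row.names = feats$gene_id)
  if ("class" %in% colnames(feats)) rd$class <- feats$class

  cd <- S4Vectors::DataFrame(barcode = barcodes, row.names = barcodes)
  mdf <- file.path(dir, "cell_metadata.tsv")
  if (file.exists(mdf)) {
    md <- utils::read.delim(mdf, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!"barcode" %in% colnames(md))
      .formatError(mdf, "missing required column: barcode", field = "barcode")
    idx <- match(barcodes, md$barcode)
    if (anyNA(idx))
      .formatError(mdf, paste("no metadata row for barcode:",
                              barcodes[which(is.na(idx))[1]]))
    for (cn in setdiff(colnames(md), "barcode")) cd[[cn]] <- md[[cn]][idx]
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), rowData = rd, colData = cd)
}

#' Write a 10x-style count directory
#'
#' Writes the \code{counts} assay and annotation of a
#' \code{SingleCellExperiment} in the plain-text dialect read by [read10x()]:
#' a 1-based MatrixMarket coordinate integer matrix, tab-separated feature and
#' cell-metadata tables and a bare barcode list. Output is byte-deterministic
#' (entries column-major sorted), so write/read/write round-trips are
#' byte-identical.
#'
#' @param sce a \code{SingleCellExperiment} with integer counts.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write10x <- function(sce, dir) {
  counts <- .assayOrStop(sce, "counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)

  t <- methods::as(methods::as(counts, "CsparseMatrix"), "TsparseMatrix")
  ord <- order(t@j, t@i)               # column-major, deterministic
  con <- file(file.path(dir, "matrix.mtx"), "wb")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(t), ncol(t), length(t@x))), con)
  if (length(t@x))
    writeLines(sprintf("%d %d %s", t@i[ord] + 1L, t@j[ord] + 1L,
                       format(t@x[ord], scientific = FALSE, trim = TRUE)),
               con)

  rd <- SummarizedExperiment::rowData(sce)
  feats <- data.frame(gene_id = rownames(sce),
                      gene_name = rd$gene_name %||% rownames(sce),
                      chromosome = rd$chromosome,
                      mito_flag = as.integer(rd$mito %||% FALSE))
  if ("class" %in% colnames(rd)) feats$class <- rd$class
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))

  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd$barcode <- colnames(sce)
  utils::write.table(cd[, c("barcode", setdiff(colnames(cd), "barcode")),
                        drop = FALSE],
                     file.path(dir, "cell_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a gene annotation table
#'
#' Reads a tab-separated gene annotation with header columns \code{gene_id},
#' \code{chromosome}, \code{mito_flag} (0/1) and optional \code{gene_name}.
#' Chromosome labels must come from the declared vocabulary (1--19, X, Y,
#' MT); duplicates and unknown labels raise format errors naming the
#' offending record.
#'
#' @param path path to the annotation TSV.
#' @return A \code{DataFrame} keyed by \code{gene_id} with columns
#'   \code{gene_name}, \code{chromosome} and logical \code{mito}.
#' @export
loadAnnotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "chromosome", "mito_flag")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    .formatError(path, paste("missing required column(s):",
                             paste(miss, collapse = ", ")),
                 field = miss[1])
  dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(dup))
    .formatError(path, paste("duplicate gene_id:", paste(dup, collapse = ", ")),
                 line = which(duplicated(tab$gene_id))[1] + 1L,
                 field = "gene_id")
  badRow <- which(!tab$chromosome %in% .chromVocabulary())
  if (length(badRow))
    .formatError(path, paste0("unknown chromosome label '",
                              tab$chromosome[badRow[1]], "'"),
                 line = badRow[1] + 1L, field = "chromosome")
  S4Vectors::DataFrame(
    gene_name = if ("gene_name" %in% colnames(tab)) tab$gene_name
                else tab$gene_id,
    chromosome = tab$chromosome,
    mito = tab$mito_flag == "1",
    row.names = tab$gene_id)
}
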