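#' @import methods
NULL

#' Planted ground truth of a simulated dataset
#'
#' Accessor for the ground truth attached by [simulateSpermatogenesis()]:
#' per-cell true stage and genotype, per-gene count-model means, the planted
#' observable trajectories of the X-linked silencing genes, and the planted
#' transition/severity categories.
#'
#' @param x a \code{SingleCellExperiment} produced by
#'   [simulateSpermatogenesis()].
#' @return A list with elements \code{cellTruth}, \code{geneTruth},
#'   \code{mu}, \code{trueProfile} and \code{trueTrajectory}.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SingleCellExperiment", function(x) {
  gt <- S4Vectors::metadata(x)$groundTruth
  if (is.null(gt)) stop("no ground truth attached: not a simulated dataset?")
  gt
})

#' Per-cell quality-control report
#'
#' Accessor for the QC report attached by [filterCells()]: one row per
#' \emph{input} cell with its three QC metrics, whether it was kept, and the
#' removal reasons.
#'
#' @param x a \code{SingleCellExperiment} returned by [filterCells()].
#' @return A data.frame with columns \code{barcode}, \code{n_genes},
#'   \code{n_umis}, \code{mito_fraction}, \code{kept}, \code{reasons}.
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname qcReport
#' @export
setMethod("qcReport", "SingleCellExperiment", function(x) {
  rep <- S4Vectors::metadata(x)$qcReport
  if (is.null(rep)) stop("no QC report attached: run filterCells() first")
  rep
})
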