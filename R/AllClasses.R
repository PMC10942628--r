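#' Quality-control thresholds for cell filtering
#'
#' Container for the three per-cell exclusion rules applied to droplet
#' scRNA-seq data: minimum number of detected genes, minimum total UMI count,
#' and maximum mitochondrial count fraction. Cells are excluded when they have
#' strictly fewer genes than \code{minGenes}, strictly fewer UMIs than
#' \code{minUMIs}, or a mitochondrial fraction strictly greater than
#' \code{maxMitoFraction}; cells sitting exactly on a boundary are retained.
#'
#' @param minGenes integer, minimum detected genes (count >= 1) per cell.
#' @param minUMIs integer, minimum total UMI count per cell.
#' @param maxMitoFraction numeric in [0, 1], maximum fraction of counts
#'   assigned to mitochondrial genes.
#'
#' @return A \code{QCThresholds} object.
#' @examples
#' QCThresholds()                      # 500 genes / 1000 UMIs / 5% mito
#' QCThresholds(minGenes = 200)
#' @export
QCThresholds <- function(minGenes = 500L, minUMIs = 1000L,
                         maxMitoFraction = 0.05) {
  new("QCThresholds", minGenes = as.integer(minGenes),
      minUMIs = as.integer(minUMIs),
      maxMitoFraction = as.numeric(maxMitoFraction))
}

#' @rdname QCThresholds
#' @export
setClass("QCThresholds",
         representation(minGenes = "integer", minUMIs = "integer",
                        maxMitoFraction = "numeric"),
         validity = function(object) {
           if (object@minGenes < 0L) return("minGenes must be >= 0")
           if (object@minUMIs < 0L) return("minUMIs must be >= 0")
           if (object@maxMitoFraction < 0 || object@maxMitoFraction > 1)
             return("maxMitoFraction must lie in [0, 1]")
           TRUE
         })

setMethod("show", "QCThresholds", function(object) {
  cat("QCThresholds: genes >=", object@minGenes,
      "| UMIs >=", object@minUMIs,
      "| mito fraction <=", object@maxMitoFraction, "\n")
})

#' Thresholds for transition and severity categorization
#'
#' Fixed cutoffs, in log-normalized expression units, used to classify each
#' X-linked gene's behaviour. A stage-transition delta greater than
#' \code{transitionHi} is called \emph{reduced silencing}, less than
#' \code{transitionLo} \emph{increased silencing}, and anything in between
#' (boundaries included) \emph{unaltered}. The mutant-minus-wild-type
#' difference at the final stage is called a \emph{strong} defect above
#' \code{severityStrong}, \emph{mild} between \code{severityMild} and
#' \code{severityStrong} (boundaries included), and \emph{no defect} below
#' \code{severityMild}.
#'
#' @param transitionHi upper transition threshold (default +1).
#' @param transitionLo lower transition threshold (default -1).
#' @param severityMild lower severity threshold (default 1).
#' @param severityStrong upper severity threshold (default 2.5).
#'
#' @return A \code{CategoryThresholds} object.
#' @examples
#' CategoryThresholds()
#' @export
CategoryThresholds <- function(transitionHi = 1, transitionLo = -1,
                               severityMild = 1, severityStrong = 2.5) {
  new("CategoryThresholds", transitionHi = as.numeric(transitionHi),
      transitionLo = as.numeric(transitionLo),
      severityMild = as.numeric(severityMild),
      severityStrong = as.numeric(severityStrong))
}

#' @rdname CategoryThresholds
#' @export
setClass("CategoryThresholds",
         representation(transitionHi = "numeric", transitionLo = "numeric",
                        severityMild = "numeric", severityStrong = "numeric"),
         validity = function(object) {
           if (object@transitionLo >= object@transitionHi)
             return("transitionLo must be < transitionHi")
           if (object@severityMild <= 0 ||
               object@severityMild >= object@severityStrong)
             return("need 0 < severityMild < severityStrong")
           TRUE
         })

setMethod("show", "CategoryThresholds", function(object) {
  cat("CategoryThresholds: transition >", object@transitionHi,
      "reduced; <", object@transitionLo, "increased\n",
      "                   severity   >", object@severityStrong,
      "strong; >=", object@severityMild, "mild\n")
})

#' Marker genes defining spermatogenic stages
#'
#' For every stage, the set of marker genes expected to be relatively high and
#' (optionally) relatively low in cells of that stage. The defaults encode the
#' standard prophase I marker logic: \emph{Stra8} marks meiotic entry at
#' pre-leptotene; \emph{Gm960} marks leptonema (SP1); zygonema (SP2) combines
#' high \emph{Dazl} with loss of \emph{Gm960} and \emph{Stra8}; pachynema
#' (SP3) combines \emph{Id4} and \emph{Shcbp1l} with declining \emph{Dazl}.
#' The pre-leptotene set is a package convention (pre-leptotene has no
#' canonical positive marker) and can be overridden freely.
#'
#' @param stages ordered character vector of stage names.
#' @param high named list (one entry per stage) of "high" marker gene IDs;
#'   every stage needs at least one.
#' @param low named list of "low" marker gene IDs; may contain empty entries.
#'
#' @return A \code{StageMarkerSet} object.
#' @examples
#' defaultMarkerSet()
#' @export
StageMarkerSet <- function(stages, high, low = NULL) {
  if (is.null(low)) low <- setNames(rep(list(character()), length(stages)),
                                    stages)
  new("StageMarkerSet", stages = as.character(stages),
      high = high[stages], low = low[stages])
}

#' @rdname StageMarkerSet
#' @export
setClass("StageMarkerSet",
         representation(stages = "character", high = "list", low = "list"),
         validity = function(object) {
           if (length(object@stages) < 2L) return("need at least two stages")
           if (anyDuplicated(object@stages)) return("duplicate stage names")
           if (!identical(names(object@high), object@stages) ||
               !identical(names(object@low), object@stages))
             return("high/low lists must be named by the stages, in order")
           n <- vapply(object@high, length, 1L)
           if (any(n < 1L))
             return(paste("every stage needs >= 1 'high' marker; missing for:",
                          paste(object@stages[n < 1L], collapse = ", ")))
           TRUE
         })

setMethod("show", "StageMarkerSet", function(object) {
  cat("StageMarkerSet over", length(object@stages), "stages\n")
  for (s in object@stages) {
    cat("  ", s, ": high {", paste(object@high[[s]], collapse = ", "), "}",
        if (length(object@low[[s]]))
          paste0(" low {", paste(object@low[[s]], collapse = ", "), "}")
        else "", "\n", sep = "")
  }
})

#' @rdname StageMarkerSet
#' @export
defaultMarkerSet <- function() {
  stages <- c("PL", "SP1", "SP2", "SP3")
  StageMarkerSet(
    stages,
    high = list(PL = c("Stra8", "Rec8"),
                SP1 = c("Gm960", "Prdm9"),
                SP2 = c("Dazl", "Sycp1"),
                SP3 = c("Id4", "Shcbp1l", "Piwil1")),
    low = list(PL = c("Gm960", "Id4", "Shcbp1l"),
               SP1 = c("Id4", "Shcbp1l", "Piwil1"),
               SP2 = c("Gm960", "Stra8", "Rec8"),
               SP3 = c("Dazl", "Stra8", "Gm960")))
}

#' Configuration of the synthetic spermatogenesis dataset
#'
#' Describes a two-genotype (wild-type \code{"WT"}, mutant \code{"MUT"})
#' spermatogenesis experiment across the ordered prophase I stages
#' pre-leptotene (PL) and spermatocytes SP1--SP3, with negative-binomially
#' distributed UMI counts, per-cell lognormal depth variation, stage marker
#' genes, stage-stable autosomal genes (including a chromosome 9 reference
#' set), mitochondrial genes, and X-linked genes whose silencing trajectories
#' are planted so that the downstream categorization recovers known truth.
#'
#' X-gene trajectories are planted directly in the units the pipeline
#' estimates: mean log1p-normalized expression per (stage, genotype). For each
#' X gene a severity class and a mutant SP2->SP3 transition category are
#' planted; both must clear their thresholds by at least \code{effectMargin}
#' log-units, and the generator numerically inverts the count model so the
#' expected observable trajectory equals the planted one.
#'
#' @param seed master seed; all randomness derives from it via fixed
#'   substreams, so identical configurations give bit-identical datasets.
#' @param nCellsPerGroup cells per (stage, genotype) group.
#' @param stages ordered stage names, pre-leptotene first.
#' @param genotypes genotype labels, wild-type first.
#' @param nXGenes,nChr9Genes,nOtherGenes,nMitoGenes gene panel sizes.
#' @param baselineMean expected counts per background (autosomal/chr9) gene in
#'   a reference-depth cell.
#' @param mitoFraction expected fraction of each cell's counts carried by the
#'   mitochondrial genes (constant across stages: mitochondrial content
#'   tracks cell RNA content).
#' @param markerBaselineMean expected counts per marker gene (markers are
#'   abundant transcripts).
#' @param baselineLogSigma gene-to-gene lognormal spread of background
#'   baselines (natural-log sd).
#' @param dispersion negative-binomial dispersion (1/size), shared by genes.
#' @param depthLognormalSigma per-cell lognormal depth sd (log scale).
#' @param markerFold fold-enrichment of a marker in its own stage (> 1).
#' @param xSeverity planted severity per X gene ("none", "mild", "strong");
#'   default: equal thirds in that order.
#' @param xTransitionCategory planted mutant SP2->SP3 category per X gene
#'   ("increased", "unaltered", "reduced"); default pairs none/increased,
#'   mild/unaltered, strong/reduced.
#' @param xBaselineLog named numeric: mean pre-leptotene expression level per
#'   severity class, in log1p-normalized units. Higher baselines for more
#'   severe classes emulate the observed tendency of highly expressed genes
#'   to show stronger silencing defects.
#' @param xBaselineJitter gene-to-gene sd around \code{xBaselineLog}.
#' @param effectMargin minimum distance (log-units) of every planted delta or
#'   difference from its category threshold; must be positive.
#' @param severityDiffTargets preferred mutant-minus-wild-type SP3 difference
#'   per severity class (log-units).
#' @param wtSilencingDepth total wild-type X silencing, PL to SP3 (log-units);
#'   trajectories decline monotonically through the stages.
#' @param wtFloor minimum wild-type SP3 expression level (log1p units), so
#'   informative genes keep detectable reads in every group.
#' @param includeContaminants also simulate spermatogonia and somatic
#'   contaminant populations (off by default).
#' @param scaleFactor library-size scale used by the paired normalization.
#'
#' @return A \code{SimulationConfig} object.
#' @examples
#' cfg <- SimulationConfig(seed = 7, nCellsPerGroup = 50, nXGenes = 24,
#'                         nChr9Genes = 20, nOtherGenes = 100)
#' cfg
#' @export
SimulationConfig <- function(seed = 1L,
                             nCellsPerGroup = 300L,
                             stages = c("PL", "SP1", "SP2", "SP3"),
                             genotypes = c("WT", "MUT"),
                             nXGenes = 240L,
                             nChr9Genes = 100L,
                             nOtherGenes = 1200L,
                             nMitoGenes = 13L,
                             baselineMean = 2.5,
                             mitoFraction = 0.025,
                             markerBaselineMean = 25,
                             baselineLogSigma = 0.3,
                             dispersion = 0.3,
                             depthLognormalSigma = 0.3,
                             markerFold = 4,
                             xSeverity = character(),
                             xTransitionCategory = character(),
                             xBaselineLog = c(none = 3.25, mild = 3.45,
                                              strong = 3.7),
                             xBaselineJitter = 0.05,
                             effectMargin = 0.5,
                             severityDiffTargets = c(none = 0, mild = 1.5,
                                                     strong = 3.2),
                             wtSilencingDepth = 3,
                             wtFloor = 0.25,
                             includeContaminants = FALSE,
                             scaleFactor = 10000) {
  if (length(xSeverity) == 0L) {
    per <- ceiling(nXGenes / 3)
    xSeverity <- rep(c("none", "mild", "strong"), each = per)[seq_len(nXGenes)]
  }
  if (length(xTransitionCategory) == 0L) {
    map <- c(none = "increased", mild = "unaltered", strong = "reduced")
    xTransitionCategory <- unname(map[xSeverity])
  }
  new("SimulationConfig", seed = as.integer(seed),
      nCellsPerGroup = as.integer(nCellsPerGroup),
      stages = as.character(stages), genotypes = as.character(genotypes),
      nXGenes = as.integer(nXGenes), nChr9Genes = as.integer(nChr9Genes),
      nOtherGenes = as.integer(nOtherGenes), nMitoGenes = as.integer(nMitoGenes),
      baselineMean = as.numeric(baselineMean),
      mitoFraction = as.numeric(mitoFraction),
      markerBaselineMean = as.numeric(markerBaselineMean),
      baselineLogSigma = as.numeric(baselineLogSigma),
      dispersion = as.numeric(dispersion),
      depthLognormalSigma = as.numeric(depthLognormalSigma),
      markerFold = as.numeric(markerFold),
      xSeverity = as.character(xSeverity),
      xTransitionCategory = as.character(xTransitionCategory),
      xBaselineLog = xBaselineLog, xBaselineJitter = as.numeric(xBaselineJitter),
      effectMargin = as.numeric(effectMargin),
      severityDiffTargets = severityDiffTargets,
      wtSilencingDepth = as.numeric(wtSilencingDepth),
      wtFloor = as.numeric(wtFloor),
      includeContaminants = isTRUE(includeContaminants),
      scaleFactor = as.numeric(scaleFactor))
}

#' @rdname SimulationConfig
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nCellsPerGroup = "integer",
                 stages = "character", genotypes = "character",
                 nXGenes = "integer", nChr9Genes = "integer",
                 nOtherGenes = "integer", nMitoGenes = "integer",
                 baselineMean = "numeric", mitoFraction = "numeric",
                 markerBaselineMean = "numeric", baselineLogSigma = "numeric",
                 dispersion = "numeric", depthLognormalSigma = "numeric",
                 markerFold = "numeric", xSeverity = "character",
                 xTransitionCategory = "character", xBaselineLog = "numeric",
                 xBaselineJitter = "numeric", effectMargin = "numeric",
                 severityDiffTargets = "numeric", wtSilencingDepth = "numeric",
                 wtFloor = "numeric", includeContaminants = "logical",
                 scaleFactor = "numeric"),
  validity = function(object) {
    if (length(object@stages) < 2L) return("need at least two stages")
    if (object@stages[1L] != "PL")
      return("stages must be ordered with the pre-leptotene stage 'PL' first")
    if (anyDuplicated(object@stages)) return("duplicate stage names")
    if (length(object@genotypes) != 2L || anyDuplicated(object@genotypes))
      return("exactly two distinct genotypes are required")
    if (object@nCellsPerGroup < 1L) return("nCellsPerGroup must be positive")
    if (object@nXGenes < 1L || object@nChr9Genes < 1L ||
        object@nOtherGenes < 1L || object@nMitoGenes < 1L)
      return("all gene-panel sizes must be positive")
    if (object@baselineMean <= 0 || object@markerBaselineMean <= 0)
      return("baseline means must be positive")
    if (object@mitoFraction <= 0 || object@mitoFraction >= 1)
      return("mitoFraction must lie strictly between 0 and 1")
    if (object@dispersion <= 0) return("dispersion must be positive")
    if (object@depthLognormalSigma < 0)
      return("depthLognormalSigma must be nonnegative")
    if (object@markerFold <= 1) return("markerFold must exceed 1")
    if (object@effectMargin <= 0)
      return("effectMargin must be > 0: planted categories must clear their thresholds strictly")
    if (object@effectMargin >= 0.75)
      return("effectMargin must be < 0.75 (the mild severity band is 1.5 log-units wide)")
    if (length(object@xSeverity) != object@nXGenes)
      return("xSeverity must have one entry per X gene")
    if (!all(object@xSeverity %in% c("none", "mild", "strong")))
      return("xSeverity entries must be 'none', 'mild' or 'strong'")
    if (length(object@xTransitionCategory) != object@nXGenes)
      return("xTransitionCategory must have one entry per X gene")
    if (!all(object@xTransitionCategory %in%
             c("reduced", "unaltered", "increased")))
      return("xTransitionCategory entries must be 'reduced', 'unaltered' or 'increased'")
    if (!all(c("none", "mild", "strong") %in% names(object@xBaselineLog)))
      return("xBaselineLog needs entries named none, mild, strong")
    if (!all(c("none", "mild", "strong") %in%
             names(object@severityDiffTargets)))
      return("severityDiffTargets needs entries named none, mild, strong")
    if (object@wtSilencingDepth <= 0) return("wtSilencingDepth must be positive")
    if (object@wtFloor <= 0) return("wtFloor must be positive")
    if (object@scaleFactor <= 0) return("scaleFactor must be positive")
    TRUE
  })

setMethod("show", "SimulationConfig", function(object) {
  ng <- object@nXGenes + object@nChr9Genes + object@nOtherGenes +
    object@nMitoGenes
  cat("SimulationConfig:",
      length(object@stages) * length(object@genotypes), "groups x",
      object@nCellsPerGroup, "cells;", ng, "genes (+ markers)\n")
  cat("  stages:", paste(object@stages, collapse = " -> "),
      "| genotypes:", paste(object@genotypes, collapse = ", "), "\n")
  cat("  X genes:", object@nXGenes, "| severity mix:",
      paste(names(table(object@xSeverity)), table(object@xSeverity),
            sep = "=", collapse = " "), "\n")
  cat("  dispersion:", object@dispersion, "| depth sigma:",
      object@depthLognormalSigma, "| marker fold:", object@markerFold,
      "| seed:", object@seed, "\n")
})
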