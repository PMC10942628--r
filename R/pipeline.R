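# End-to-end pipeline: simulate-or-load -> QC -> normalize -> stage ->
# silencing statistics -> categorization -> report, with deterministic
# CSV/JSON outputs.

#' Assemble a pipeline configuration
#'
#' Bundles the configuration of every pipeline step. Either a simulation
#' config (the default) or an input directory of 10x-style files must be
#' given.
#'
#' @param simulation a [SimulationConfig()] (ignored when \code{inputDir} is
#'   set).
#' @param inputDir optional directory readable by [read10x()]; cell metadata
#'   must provide \code{genotype} labels.
#' @param qc a [QCThresholds()].
#' @param thresholds a [CategoryThresholds()].
#' @param markers a [StageMarkerSet()].
#' @param stageMode \code{"markers"} or \code{"provided"}; the provided mode
#'   uses the \code{true_stage} (simulation) or \code{stage} (input
#'   metadata) column.
#' @param ratioDenominator \code{"chr9"} or \code{"all_autosomes"}.
#' @param scaleFactor normalization scale.
#' @return A list of class \code{msciPipelineConfig}.
#' @export
pipelineConfig <- function(simulation = SimulationConfig(), inputDir = NULL,
                           qc = QCThresholds(),
                           thresholds = CategoryThresholds(),
                           markers = defaultMarkerSet(),
                           stageMode = c("markers", "provided"),
                           ratioDenominator = c("chr9", "all_autosomes"),
                           scaleFactor = 10000) {
  structure(list(simulation = simulation, inputDir = inputDir, qc = qc,
                 thresholds = thresholds, markers = markers,
                 stageMode = match.arg(stageMode),
                 ratioDenominator = match.arg(ratioDenominator),
                 scaleFactor = scaleFactor),
            class = "msciPipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Nested keys mirror the arguments of [pipelineConfig()]: top-level
#' sections \code{simulation}, \code{qc}, \code{thresholds}, \code{staging}
#' (\code{mode}), \code{ratio} (\code{denominator}), \code{input_dir},
#' \code{scale_factor}. Unset keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A \code{msciPipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(SimulationConfig, c(list(), y$simulation))
  qc <- do.call(QCThresholds, c(list(), y$qc))
  thr <- do.call(CategoryThresholds, c(list(), y$thresholds))
  pipelineConfig(simulation = sim, inputDir = y$input_dir, qc = qc,
                 thresholds = thr,
                 stageMode = y$staging$mode %||% "markers",
                 ratioDenominator = y$ratio$denominator %||% "chr9",
                 scaleFactor = y$scale_factor %||% 10000)
}

.writeCsv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
}

#' Run the full silencing-dynamics pipeline
#'
#' Executes simulate-or-load, cell QC, normalization, stage assignment,
#' X:autosome ratios with the final-stage genotype comparison, informative-
#' gene selection, pre-leptotene-normalized trajectories, categorization
#' with per-transition Fisher tests, the severity-versus-baseline trend and
#' the pseudobulk correlation matrix. With an output directory, writes
#' \code{qc_report.csv}, \code{stage_assignments.csv}, \code{ratios.csv},
#' \code{trajectory.csv}, \code{categories.csv}, \code{severity.csv},
#' \code{contingency.csv}, \code{correlation.csv} and \code{summary.json};
#' outputs are byte-deterministic for a fixed configuration.
#'
#' @param config a [pipelineConfig()] (or [readPipelineConfig()] result).
#' @param outDir optional output directory.
#' @return Invisibly, a list with the intermediate and final results
#'   (\code{sce}, \code{ratios}, \code{ratioTest}, \code{informative},
#'   \code{trajectory}, \code{categories}, \code{correlation},
#'   \code{summary}).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "msciPipelineConfig"))
  sce <- if (!is.null(config$inputDir)) read10x(config$inputDir)
         else simulateSpermatogenesis(config$simulation)
  genos <- if (!is.null(config$inputDir))
    unique(SummarizedExperiment::colData(sce)$genotype)
  else config$simulation@genotypes

  sce <- filterCells(sce, config$qc)
  sce <- logNormalizeCounts(sce, config$scaleFactor)

  stages <- config$markers@stages
  if (config$stageMode == "provided") {
    cd <- SummarizedExperiment::colData(sce)
    lab <- if ("true_stage" %in% colnames(cd)) cd$true_stage else cd$stage
    sce <- assignStages(sce, config$markers, mode = "provided", labels = lab)
  } else {
    sce <- assignStages(sce, config$markers, mode = "markers")
  }
  cd <- SummarizedExperiment::colData(sce)
  cd$genotype <- factor(cd$genotype, levels = genos)
  SummarizedExperiment::colData(sce) <- cd

  ratios <- xAutosomeRatio(sce, denominator = config$ratioDenominator)
  lastStage <- stages[length(stages)]
  atLast <- cd$stage == lastStage
  ratioTest <- compareRatioDistributions(
    ratios[atLast & cd$genotype == genos[1L]],
    ratios[atLast & cd$genotype == genos[2L]])

  informative <- selectInformativeGenes(sce, "X")
  profile <- stageGenotypeMeans(sce)
  trajectory <- normalizeToPreleptotene(profile, informative)
  plMeans <- with(profile[profile$stage == stages[1L] &
                            profile$genotype == genos[1L], ],
                  stats::setNames(mean, gene))
  cats <- categorizeGenes(trajectory, config$thresholds, plMeans = plMeans)
  corr <- pseudobulkCorrelation(sce)

  counts <- lapply(cats$contingency, function(tab)
    as.data.frame(as.table(tab), stringsAsFactors = FALSE))
  summary <- list(
    n_cells_kept = ncol(sce),
    n_informative_genes = length(informative),
    ratio = list(denominator = config$ratioDenominator,
                 last_stage = lastStage,
                 wilcoxon_W = ratioTest$statistic,
                 wilcoxon_p_two_sided = ratioTest$p.value,
                 n_undefined = attr(ratios, "nUndefined")),
    transition_counts = lapply(cats$contingency, function(tab)
      apply(tab, 1L, as.list)),
    fisher_p = as.list(cats$fisher),
    severity_counts = as.list(table(cats$severity$severity)),
    severity_trend = if (!is.null(cats$trend))
      list(statistic = cats$trend$statistic, p_one_sided = cats$trend$p.value,
           method = cats$trend$method),
    note = paste("Per-transition Fisher p-values are reported without",
                 "multiple-testing correction across transitions."))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeCsv(qcReport(sce), outDir, "qc_report.csv")
    sa <- as.data.frame(cd[, grep("^barcode$|^genotype$|^stage$|^score_",
                                  colnames(cd)), drop = FALSE])
    .writeCsv(sa, outDir, "stage_assignments.csv")
    .writeCsv(data.frame(barcode = names(ratios), ratio = unname(ratios),
                         stage = as.character(cd$stage),
                         genotype = as.character(cd$genotype)),
              outDir, "ratios.csv")
    .writeCsv(merge(trajectory$values,
                    merge(trajectory$deltas, trajectory$diffs, by = "gene"),
                    by = c("gene", "genotype")),
              outDir, "trajectory.csv")
    .writeCsv(cats$transitions, outDir, "categories.csv")
    .writeCsv(cats$severity, outDir, "severity.csv")
    ct <- do.call(rbind, lapply(names(counts), function(tr)
      cbind(transition = tr, counts[[tr]],
            fisher_p = cats$fisher[[tr]])))
    colnames(ct) <- c("transition", "genotype", "category", "n_genes",
                      "fisher_p")
    .writeCsv(ct, outDir, "contingency.csv")
    cm <- as.data.frame(corr)
    cm <- cbind(group = rownames(corr), cm)
    .writeCsv(cm, outDir, "correlation.csv")
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(sce = sce, ratios = ratios, ratioTest = ratioTest,
                 informative = informative, trajectory = trajectory,
                 categories = cats, correlation = corr, summary = summary))
}
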