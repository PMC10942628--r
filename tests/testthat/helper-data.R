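# Shared fixtures, generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, build) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, build(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

smallConfig <- function(seed = 7, ...) {
  args <- list(seed = seed, nCellsPerGroup = 50, nXGenes = 24,
               nChr9Genes = 20, nOtherGenes = 120)
  override <- list(...)
  args[names(override)] <- override
  do.call(SimulationConfig, args)
}

# small simulated dataset, QC'd, normalized and truth-staged
smallDataset <- function() cachedFixture("small", function() {
  sce <- simulateSpermatogenesis(smallConfig())
  sce <- logNormalizeCounts(filterCells(sce, QCThresholds(minGenes = 50,
                                                          minUMIs = 100)))
  assignStages(sce, mode = "provided",
               labels = SummarizedExperiment::colData(sce)$true_stage)
})

# full pipeline under the default study conditions (240 X genes, 80 per
# category, 300 cells per group, dispersion 0.3, fixed seed)
defaultRun <- function() cachedFixture("defaultRun", function() {
  suppressWarnings(runPipeline(pipelineConfig(
    simulation = SimulationConfig(seed = 3))))
})

# larger groups (500 cells per group) for the distribution-level checks
largeRun <- function() cachedFixture("largeRun", function() {
  suppressWarnings(runPipeline(pipelineConfig(
    simulation = SimulationConfig(seed = 3, nCellsPerGroup = 500))))
})

# tiny SingleCellExperiment built directly from a dense count matrix
toySCE <- function(counts, chromosome = NULL, mito = NULL, genotype = NULL,
                   stage = NULL) {
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(counts)))
  cells <- colnames(counts)
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cells)
  if (is.null(chromosome)) chromosome <- rep("1", nrow(counts))
  if (is.null(mito)) mito <- chromosome == "MT"
  cd <- S4Vectors::DataFrame(barcode = cells, row.names = cells)
  if (!is.null(genotype)) cd$genotype <- genotype
  if (!is.null(stage)) cd$stage <- stage
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(gene_id = genes, gene_name = genes,
                                   chromosome = chromosome, mito = mito,
                                   row.names = genes),
    colData = cd)
}
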