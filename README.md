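# msciDynamics

Quantifying the dynamics of meiotic sex chromosome inactivation (MSCI) from
staged spermatogenesis single-cell RNA-seq.

During male meiotic prophase I the X and Y chromosomes are transcriptionally
silenced: silencing initiates around leptonema and must be actively
maintained through pachynema. Spermatocytes that fail to maintain it arrest
and die. Given droplet scRNA-seq of germ cells from two genotypes (a
wild-type and a mutant), this package asks *where along prophase I silencing
fails*, gene by gene, and tests whether the two genotypes differ.

It is aimed at reproductive-genomics analysts who have 10x-style count
matrices with per-cell genotype labels (and optionally precomputed stage
labels) and want a deterministic, testable version of the standard
MSCI-dynamics analysis.

## The analysis

For cells passing quality control (< 500 detected genes, < 1000 UMIs, or
> 5% mitochondrial reads excluded; boundaries retained) and counts-per-10,000
log-normalized, `v = ln(1 + 10^4 * count / total)`:

- **Stage assignment.** Each cell is scored against marker-gene panels for
  pre-leptotene (PL) and spermatocytes SP1 (leptonema, *Gm960*), SP2
  (zygonema, high *Dazl* / low *Gm960*) and SP3 (pachynema, *Id4*,
  *Shcbp1l*); the score of a stage is the mean z-scored expression of its
  "high" markers minus that of its "low" markers, and cells take the argmax
  stage. Externally provided labels are accepted instead.
- **X:autosome ratio.** Per cell, the mean log-normalized expression of all
  X-linked genes divided by the mean over chromosome 9 genes (or all
  autosomes); distributions are compared between genotypes with a two-sided
  Wilcoxon rank-sum test. The ratio falls as MSCI proceeds.
- **Trajectories.** For every informative X-linked gene (reads in every
  stage x genotype group), the per-group mean expression is re-expressed
  relative to its own pre-leptotene level (log-unit subtraction, PL = 0).
- **Categorization.** Each stage transition delta `d` is classified as
  reduced silencing (`d > 1`), increased silencing (`d < -1`) or unaltered
  (otherwise, boundaries included); genotype-by-category tables per
  transition are tested with an exact Fisher r x c test (full enumeration of
  margin-preserving tables). The mutant-minus-wild-type difference at SP3
  grades each gene's silencing defect: strong (`> 2.5`), mild (`in [1,
  2.5]`) or none (`< 1`), and the tendency of highly expressed genes to have
  more severe defects is tested with a Jonckheere-Terpstra ordered trend on
  pre-leptotene expression.
- **Synthetic data.** A negative-binomial simulator plants known silencing
  trajectories — monotone decline in the wild type, incomplete SP3 silencing
  in the mutant — directly in the log-normalized units the pipeline
  estimates, so every gene's true category is known and the whole analysis
  is verifiable end to end without any external dataset.

## Worked example

```r
library(msciDynamics)
cfg <- pipelineConfig(simulation = SimulationConfig(seed = 1,
                                                    nCellsPerGroup = 100))
res <- runPipeline(cfg)

cd <- SummarizedExperiment::colData(res$sce)
length(res$informative)
#> [1] 241
round(tapply(res$ratios, list(as.character(cd$stage), cd$genotype),
             median)[c("PL", "SP1", "SP2", "SP3"), ], 2)
#>       WT  MUT
#> PL  7.66 7.78
#> SP1 2.34 2.35
#> SP2 1.35 1.35
#> SP3 0.28 1.69
res$ratioTest$p.value
#> [1] 2.56e-34
res$categories$contingency$SP2_SP3
#>     reduced unaltered increased
#> WT        0         1       240
#> MUT      80        81        80
signif(res$categories$fisher[["SP2_SP3"]], 3)
#> [1] 5.2e-65
table(res$categories$severity$severity)
#>   none   mild strong
#>     81     80     80
```

Reading the output: 241 X-linked genes are informative (the 240 planted
silencing genes plus the X-linked marker *Gm960*). The wild-type X:chr9
ratio falls monotonically from pre-leptotene to SP3 (7.66 to 0.28) — MSCI in
action — while the mutant ratio stays high at SP3 (1.69), and the genotype
difference at SP3 is overwhelming (Wilcoxon p ~ 1e-34). At the SP2 to SP3
transition the wild type keeps silencing (240/241 genes "increased") while
the mutant de-represses (80 "reduced"), with Fisher p ~ 5e-65; severity
calls split 81/80/80 across none/mild/strong, exactly the planted design.

`runPipeline(cfg, "outdir")` additionally writes `qc_report.csv`,
`stage_assignments.csv`, `ratios.csv`, `trajectory.csv`, `categories.csv`,
`severity.csv`, `contingency.csv`, `correlation.csv` and `summary.json`,
byte-identical across reruns of the same configuration. A shell wrapper
lives at `inst/scripts/msci-pipeline.R` with an example YAML config in
`inst/extdata/example_config.yaml`.

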