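---
title: "Quantifying MSCI silencing dynamics: methods and design notes"
author: "msciDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MSCI silencing dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the model

Meiotic sex chromosome inactivation (MSCI) silences the X and Y chromosomes
during male meiotic prophase I. Silencing initiates around leptonema and is
actively maintained into pachynema; a mutant may initiate silencing normally
yet fail to maintain it. This package turns that question into a concrete,
fully testable computation on staged single-cell RNA-seq of germ cells from
two genotypes.

All expression values live on one fixed scale: counts-per-10,000
log-normalized expression, \(v_{jc} = \ln(1 + 10^4\, x_{jc} / T_c)\) for
count \(x_{jc}\) of gene \(j\) in cell \(c\) with library size \(T_c\). The
scale matters because every downstream threshold (the \(\pm 1\) transition
cutoffs, the 1 and 2.5 severity cutoffs) is interpreted in these log units.

Per gene, stage \(s\) and genotype \(g\) the pipeline computes the group
mean \(\bar v_j(s, g)\), then re-expresses it relative to the gene's own
pre-leptotene (PL) level:

\[ u_j(s, g) = \bar v_j(s, g) - \bar v_j(\mathrm{PL}, g), \]

so every trajectory starts at exactly 0 and negative values mean silencing.
Transition deltas \(d = u(s_{k+1}) - u(s_k)\) are categorized as *reduced
silencing* (\(d > 1\)), *increased silencing* (\(d < -1\)) or *unaltered*
(boundaries included, per the band definition "\(\ge -1\) and \(\le 1\)").
The genotype contrast at the last stage, \(\Delta_j = u_j(\mathrm{SP3},
\mathrm{mut}) - u_j(\mathrm{SP3}, \mathrm{wt})\), grades the silencing
defect: *strong* (\(\Delta > 2.5\)), *mild* (\(1 \le \Delta \le 2.5\)),
*none* (\(\Delta < 1\)). The sign convention (mutant minus wild-type) makes
failure to silence positive, matching the severity labels' direction.

Whether "normalized to pre-leptotene" means log-scale subtraction or
linear-scale division is a genuine ambiguity; we use log subtraction because
the upstream values are log-transformed and the categorization thresholds
are only mutually consistent on a single scale. The convention is isolated
in `normalizeToPreleptotene()`, so a linear-ratio variant could be swapped
in without touching the categorizer.

Only *informative* genes are categorized: genes of the target chromosome
with at least one raw read in at least one cell of **every** stage-genotype
group. Raw counts (not normalized values) define detection; for integer
counts the two readings coincide.

# Tests attached to the categories

* **Per-transition genotype contrast.** A 2 (genotype) by 3 (category) table
  per transition, tested with an exact conditional Fisher test: the p-value
  is the total multivariate-hypergeometric probability of all
  margin-preserving tables whose probability does not exceed the observed
  table's, with a relative slack of 1e-7 absorbing floating-point ties.
  Tables are enumerated exhaustively (for 2x3 tables of a few hundred genes
  this is ~10^4 tables). An all-zero category column is dropped before
  enumeration — an unobserved category carries no information — and the
  degenerate p = 1 convention (with a warning) is reserved for an all-zero
  genotype row or a table with fewer than two surviving columns. No
  correction across the three transitions is applied; per-transition
  p-values are reported as such, with a footnote in the JSON summary.
* **X:autosome ratio.** Per cell, mean \(v\) over all annotated X genes
  (zeros included — the chromosome gene set, not the detected set) divided
  by the mean over chromosome 9 genes. Chromosome 9 is the default
  reference; `denominator = "all_autosomes"` is supported because the two
  natural readings of the method differ, and both are defensible. Cells with
  a zero denominator yield missing ratios with a warning, never a hard
  failure. Genotype contrasts use the two-sided Wilcoxon rank-sum test:
  exact enumeration when the smaller sample has at most 8 observations and
  there are no ties, otherwise the normal approximation with tie and
  continuity corrections.
* **Severity-baseline trend.** The observation that highly expressed genes
  tend to have more severe defects is tested with a Jonckheere-Terpstra
  ordered trend of PL expression across none < mild < strong. Any ordered
  trend test would do; JT was chosen because it is the canonical rank test
  for ordered groups and needs no distributional assumptions. The exact
  permutation distribution is used up to n = 12 (all distinct group
  assignments enumerated), the tie-corrected normal approximation with a
  0.5 continuity correction beyond.

# Stage assignment

The reference analyses assign stages by unsupervised clustering followed by
manual marker annotation. Clustering is non-deterministic glue; the biology
enters only through the markers. We therefore score each cell directly: per
gene, z-score \(v\) across all cells (zero-variance genes contribute 0); the
score of stage \(s\) is the mean z of its "high" markers minus the mean z of
its "low" markers; cells take the argmax stage, ties broken toward the
earlier stage. Precomputed labels can be passed through instead
(`mode = "provided"`), feeding identical downstream code.

Two design points deserve note. First, every default stage panel contains
both high and low markers: a per-cell shift common to all genes (for
example, the global inflation of normalized values in late stages when a
large silenced gene mass redistributes library mass) then cancels in the
high-minus-low difference. Second, pre-leptotene has no canonical positive
marker in the literature, so its default panel (high *Stra8*, *Rec8*; low
*Gm960*, *Id4*, *Shcbp1l*) is a package convention and is explicitly
overridable; the remaining panels follow the standard prophase I logic
(*Gm960*, *Prdm9* for leptonema; *Dazl*, *Sycp1* up / *Gm960* down for
zygonema; *Id4*, *Shcbp1l*, *Piwil1* up / *Dazl* down for pachynema).

# The synthetic-data generator

The generator exists so that every claim the pipeline makes is checkable
against known truth. It emulates a two-genotype spermatogenesis experiment:

* ordered stages PL, SP1, SP2, SP3, two genotypes, `nCellsPerGroup` cells
  per group (default 300);
* negative-binomial UMI counts with a gene-shared dispersion (default 0.3,
  a typical droplet-data value) and a per-cell lognormal depth factor
  (log-sd 0.3);
* 240 X-linked silencing genes, 100 chromosome 9 reference genes, 1200
  stage-stable autosomal genes, 13 mitochondrial genes and 9 marker genes;
* stage markers enriched `markerFold`-fold (default 4) in their own stage
  with off-stage repression mirroring their biology;
* a mitochondrial pool holding a constant fraction (default 2.5%) of each
  cell's library, because mitochondrial content tracks cell RNA content —
  without this, late-stage cells would spuriously fail the 5% mito QC rule
  simply because X silencing shrinks their nuclear library;
* optional spermatogonia/somatic contaminant populations, off by default.

**Planting in observable units.** Trajectories are planted directly as
target group means in log-normalized units, the same units the pipeline
estimates, so the planted categories line up with the thresholds without
any conversion. Wild-type X genes decline monotonically (cumulative
fractions 0, 0.2, 7/15, 1 of a total depth of up to 3 log-units); the
mutant matches the wild type through SP2 and realizes, per gene, a planted
(SP2-to-SP3 category, severity) pair. The admissible final-transition delta
is the intersection of the category interval and the severity interval,
both shrunk by `effectMargin` (default 0.5 log-units) so every planted call
clears its threshold strictly; an empty intersection (for example
"reduced" with "none": a gene cannot de-repress by more than a log-unit yet
differ from the wild type by less than one) is a configuration error. PL
baselines are drawn per severity class (defaults 3.25/3.45/3.7 log-units
for none/mild/strong, jitter 0.05) — more severe classes sit higher,
emulating the observed coupling between baseline expression and defect
severity, and giving deep wild-type silencing the headroom it needs.

**Inverting the observation model.** A target mean \(m\) in log1p units is
converted to a count-space mean by solving \(\mathrm{E}[\ln(1 + \kappa
X)] = m\) for \(X \sim \mathrm{NB}(\mu, 1/\phi)\), where \(\kappa = 10^4 /
S\) and \(S\) is the group's expected library size. The expectation is
computed by truncated NB summation (tail mass below 1e-11) on a 260-point
log-spaced \(\mu\) grid and inverted by monotone interpolation. Because
\(S\) itself depends on the X means, the library size and the inversion are
iterated to a fixed point (relative change below 1e-5, typically ~15
rounds). The per-cell depth factor is not integrated in the inversion; for
abundant genes it cancels through the library size, and the residual bias
at low means is a few hundredths of a log-unit, small against the 0.5
planted margins.

The ground truth records the per-cell stage/genotype, the per-gene
count-space means per group, the planted observable trajectories, and the
planted categories; by construction, applying the package's own categorizer
to the true trajectories reproduces the planted categories for every gene.

**What the generator does not emulate.** No doublets, ambient RNA,
cell-cycle structure, batch or chemistry effects beyond depth variation; no
genuinely heterogeneous early transitions (mutant and wild type coincide
through SP2, so early-transition contingency tables are degenerate and
their Fisher p is 1 by the zero-margin convention); marker genes behave
identically in both genotypes. The gene panel is ~1,500 genes rather than a
~20,000-gene transcriptome, so each gene's normalized share is inflated
roughly 13-fold relative to genome-wide data; the planted X genes
correspond to the well-expressed informative subset on which trajectory
magnitudes of 1-3 log-units are attainable at all. Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
signal under realistic noise — not robustness to every artifact of real
droplet data.

# Determinism and numerical conventions

* One master seed; every stochastic draw comes from a substream seeded by a
  fixed integer mix of (seed, group, gene), with the RNG kind pinned
  (Mersenne-Twister / Inversion / Rejection), so identical configurations
  give bit-identical datasets across platforms and later groups do not
  perturb earlier draws.
* MatrixMarket files are written with column-major-sorted integer triplets,
  making write/read/write byte-identical; 1-based file indices are
  converted at the boundary only. Mitochondrial genes are identified by an
  explicit flag column, not by name prefix.
* QC boundaries: all three rules are strict inequalities for exclusion, so
  a cell at exactly 500 genes, 1000 UMIs and 5.0% mito is retained; "genes"
  means genes with count >= 1 in the cell; mito fraction is mito counts over
  total counts, 0 for an empty cell.
* Category boundaries: \(\pm 1\) belong to "unaltered"; 1 and 2.5 belong to
  "mild".
* Stage-score ties break toward the earlier stage; all-identical cells give
  all-zero scores and fall to PL.
* Normalization requires positive library sizes and errors with the
  offending barcode if QC has not run; conservation \(\sum_j (e^{v_{jc}} -
  1) = 10^4\) holds to 1e-6 relative and is asserted in the tests.

# Problem sizes used by the test suite

The default simulated conditions are 240 X genes (80 per planted category),
300 cells per group and dispersion 0.3; distribution-level checks use 500
cells per group, staging recovery 200, and unit tests run on a reduced
panel (24 X genes, 50 cells per group). These sizes were chosen so that
group-mean noise (standard error ~0.03 log-units at 500 cells) is small
against the 0.5 planted margins while the whole suite stays quick to run.

# Known limitations

* The marker scorer is a deterministic stand-in for cluster-then-annotate
  stage calling; on real data with rare intermediate cells its hard argmax
  may be less forgiving than manual cluster curation, which is why provided
  labels are a first-class input.
* Severity is graded at the last configured stage only; a defect confined
  to earlier stages would surface in the transition categories but not in
  the severity call.
* With the log-subtraction convention, trajectory magnitudes are bounded by
  a gene's baseline level, so severity categories beyond "mild" are only
  observable for well-expressed genes — a property shared by any analysis
  on this scale, and the reason informative-gene selection and the
  baseline-severity trend exist.
* The exact Fisher enumeration is exhaustive; for tables much larger than
  the 2x3 genotype-by-category case (say many rows and columns with large
  totals) it would become slow, and a network-algorithm implementation
  would be preferable.
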