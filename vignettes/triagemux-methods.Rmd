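---
title: "Methods: barcode multiplexing and density-peak cell typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode multiplexing and density-peak cell typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagemux)
```

# Overview

`triagemux` implements the computational workflow of a multiplexed iPSC
differentiation experiment built on *transcribed genomic barcodes*: short
DNA sequences integrated at a safe-harbour locus and expressed within a
reporter transcript, so that every sequenced cell can be assigned back to
its sample of origin without exogenous labelling. Around that core the
package provides the downstream single-cell machinery the design enables:
demultiplexing rules, repressive-tendency (RTS) weighted density-peak cell
typing, gene-program parsing over an epigenetic reference, and
reference-based annotation — plus synthetic-data generators emulating
every input, so the whole pipeline runs and is tested offline.

This vignette records the models, conventions and numerical choices, in
particular where a published description left the behaviour open and the
package had to commit to one.

# Barcode design

Candidate barcodes are drawn i.i.d. uniformly over A/C/G/T (default
10,000 candidates of 15 nt). A candidate is discarded when it starts or
ends with a stop codon (TAA, TAG, TGA) or contains a homopolymer run of
four or more identical bases. "Repetitive runs" is read as *homopolymer*
runs — the common barcode-design meaning; a stricter dinucleotide-repeat
reading can be emulated by lowering `max_homopolymer` or post-filtering,
but is not the default. Selection is a deterministic greedy scan in
candidate order: a candidate is admitted iff its Hamming distance to every
already-admitted barcode is at least `min_hamming` (default 5), stopping
at `k_select` (default 18). Greedy scanning is not guaranteed to find a
maximum-size code, but it is simple, reproducible, and the constraint set
is loose enough at these sizes that 18 barcodes are reliably found from
10,000 candidates.

The packaged `ipsc_barcodes()` set (BC01–BC18) validates against all of
these constraints; its observed minimum pairwise Hamming distance is 6.

Cassette assembly concatenates configurable flanks around the barcode:
EcoRV 3' half (`ATC`), MluI site (`ACGCGT`), the reverse complement of a
partial Read2 adaptor (default 31 nt, chosen so the full single-stranded
oligo is exactly 60 nt), the 15-nt barcode, and an MluI-completing
overhang. Only the structure is asserted by validation; every flank is
configuration, since the exact adaptor truncation is a wet-lab choice.

# Demultiplexing

Two rules are provided.

**Max-count rule.** Per cell: all-zero row → `Negative`; unique argmax →
that barcode; tied maxima → `Doublet`. This is exact and parameter-free.

**Quantile-threshold rule.** A fully specified variant of the
hashing-demultiplexer family:

1. counts are CLR-transformed per barcode (log1p, centred per column);
2. cells are grouped into `n_barcodes + 1` clusters by k-medoids
   (`cluster::clara`) on the CLR matrix;
3. for each barcode, the cluster with the lowest mean raw count is taken
   as background and a negative binomial is fitted by method of moments
   (Poisson fallback when the sample variance does not exceed the mean;
   an all-zero background yields threshold 0 with a warning);
4. a cell is *positive* for a barcode when its raw count strictly exceeds
   the background distribution's `q`-quantile (default `q = 0.99`);
   0/1/2+ positives give `Negative` / the barcode / `Doublet`.

Ties at the threshold count as not positive ("exceeds" is strict). At
`q = 1` every non-degenerate threshold is infinite and all cells are
`Negative`. Because the positivity thresholds are integer quantiles of
discrete fits, the realised per-barcode false-positive rate moves in
steps; singlet recall on the simulated study conditions (signal mean 200,
ambient mean 2, 5% doublets, 2,000 cells, 8 tags) is therefore a
distribution around ~0.95 across seeds rather than a constant.

**Agreement.** Two label vectors agree on a cell when both give the same
sample label (double positive) or both are `Negative` (double negative);
the agreement statistic is (double positives + double negatives) / total
cells. Doublet calls never contribute — the stricter same-sample reading
of "double positive" is used. QC bounds ("between X and Y") are closed
intervals; all bounds are optional and violations are enumerated per
cell.

# RTS weighting and the discordance transform

The repressive tendency score is a per-gene, non-negative scalar derived
upstream from the breadth of H3K27me3 domains across many tissues; genes
with broad repressive domains across contexts tend to be cell-identity
regulators. The package consumes an RTS table as input and never
recomputes it.

* **Discordance score (DS)**: expression × RTS, per gene. Genes absent
  from the RTS table get DS 0 (zero-filling keeps matrix shapes stable;
  dropped genes would change ranks only below any top-k cut of interest).
* **Per-cell weight**: the maximum RTS among genes the cell expresses
  (strictly positive by default; threshold configurable). The weight
  depends only on the expressed-gene support, not magnitudes.
* **Top-k DS genes** (default k = 100) are ranked descending with
  lexicographic tie-break for determinism.
* Peak similarity uses the Jaccard index of top-k lists; peaks are
  clustered by complete linkage on Euclidean distances between the rows
  of the Jaccard matrix.

# Density-peak cell typing

The cell-typing algorithm replaces graph-clustering resolution tuning
with a density criterion: cell types are local maxima of the RTS-weighted
density over a 2-D embedding (the embedding itself — typically UMAP — is
an input, not computed here).

1. **Weighted KDE.** Gaussian kernels centred at every cell, weights
   normalised to sum to one, kernel covariance = (weighted coordinate
   covariance) × `bandwidth²` with default bandwidth 0.25 — the
   covariance-factor convention of the standard Gaussian KDE
   implementations. The *maximum-likelihood* (population) weighted
   covariance is used, which makes the density exactly invariant under
   duplicating cells with split weights; with uniform weights the
   estimate equals the unweighted KDE exactly. Density is evaluated at
   cell positions; cells, not grid nodes, are clustered.
2. **Contour levels.** `n_levels` (default 10) thresholds equally spaced
   strictly between the minimum and maximum density, mirroring default
   contour-plot behaviour. Super-threshold cell sets are nested by
   construction.
3. **Per-level spatial clustering.** DBSCAN over the super-threshold
   cells in embedding coordinates. No DBSCAN implementation ships with
   the environment's R packages, so the package provides a direct
   O(n²) distance-matrix implementation (adequate at desk scale, and
   verified against a breadth-first-search oracle). Defaults:
   `eps = bandwidth` (the same length scale as the smoothing) and
   `min_samples = 5`; both recorded in output provenance since any
   original values are unstated.
4. **Peak finding.** Clusters across levels are linked into a
   containment forest: each cluster's parent is the cluster at the level
   below holding the plurality of its cells (plurality linking is robust
   to noise-cell dropout and equivalent to geometric containment for
   nested thresholds). "No smaller clusters within them at higher
   levels" is formalised as *the branch never splits*: a peak is the
   topmost cluster of a maximal chain, and its membership is the cell
   set at that birth level (a flag-worthy alternative — union over the
   branch — was not adopted; birth level gives the larger, more
   inclusive cell set of the unsplit branch). Peaks with fewer than
   `min_peak_cells` (default 20, matching the annotation filter) are
   dropped; remaining cells are `NONE`.

A practical note on bandwidth: the kernel covariance scales the *global*
coordinate covariance, so a single tight blob occupying the whole
embedding is smoothed much less (relative to its own spread) than the
same blob inside a larger landscape. On compact single-population
embeddings a larger bandwidth (e.g. 0.5) may be needed for a single
coherent peak.

# Gene-program parsing

The top DS genes of a peak are parsed into co-regulated programs against
an epigenetic reference basis:

1. **Basis.** PCA on the gene × cell-type H3K27me3 breadth matrix
   (feature-centred, unscaled; breadths are used untransformed by
   default, with an optional log1p exposed). Components are retained
   either as a fixed count (as for the published 67-component Roadmap
   basis) or by a cumulative-variance rule (default 0.96) so synthetic
   references of any rank work. The real Roadmap matrix is an optional
   external input, never required.
2. **GMM/BIC.** Projected gene scores are clustered by Gaussian mixtures
   with the component count k (default range 1–10) chosen by BIC, via
   `mclust`. The covariance family is itself selected by BIC among a
   small hierarchy (full `VVV`, diagonal `VVI`/`VII`, spherical `EII`):
   fixing the full-covariance family and falling back per-k when it is
   not estimable would make BIC values non-comparable across k and
   systematically inflate the chosen k. `mclust`'s deterministic
   hierarchical initialisation replaces random restarts, so results are
   reproducible without a seed sweep. Degenerate (zero-variance) score
   matrices short-circuit to a single component.
3. **PPI filter.** A program is kept when its members share
   significantly many protein-protein-interaction edges: a one-tailed
   upper hypergeometric test (p < 0.001) whose population is all
   unordered gene pairs over the background, successes the background
   edge set, and draws the program's internal pairs. The sampling frame
   is a package decision; the edge list itself is an input (e.g. a
   STRING export), never downloaded.
4. **Term enrichment.** Per term, the upper-tail hypergeometric
   probability of the observed overlap, BH-adjusted across tested
   terms; kept at FDR < 0.01. All hypergeometric tails are inclusive of
   the observed value, P(X ≥ obs) — stated because conventions differ.

# Annotation

* **Module scores**: mean expression of a gene set minus that of pooled
  control genes drawn from expression-matched bins (24 bins, 100
  controls per set gene, seeded). Controls are drawn from the *non-set*
  genes of the bin (falling back to the whole bin if the set fills it);
  with small gene universes this matters, since set genes can dominate
  the top bins. This is a self-contained variant of binned-control
  scoring; numerical equality with other implementations is not
  promised.
* **Thresholded argmax labelling**: a cell takes its highest-scoring
  label iff the score strictly exceeds the threshold (0 for module
  scores, 0.5 for externally produced label-transfer scores); argmax
  ties give NA.
* **Peak majority labels**: a peak is NA unless strictly more than half
  its cells are labelled; otherwise the modal label, with modal ties
  resolving to NA. All tie conventions resolve conservatively to NA.
* **Spatial matching**: peak mean profiles over a marker union are
  matched to reference domain profiles by Pearson correlation, after
  dropping peaks with fewer than 20 cells and genes expressed in less
  than 5% of the cells of any *retained* peak (the filter is applied
  over retained peaks, not all peaks).

# Synthetic data: what it emulates, and what it does not

The generators plant known truth and serialise it with all parameters:

* `simulate_barcode_counts` — Poisson signal/ambient counts over a
  default panel of 8 tags (an 8-sample hashing design; the
  quantile-threshold rule is the method used for hashing libraries),
  with 5% doublets, 2% negatives, signal mean 200 and ambient mean 2 as
  the reference conditions.
* `simulate_typed_expression` — cell types as isotropic Gaussian blobs
  (sd 0.5) whose centres sit 10 blob-sds apart on a circle; 5 marker
  genes per type with negative-binomial expression (mean 20 in-type,
  0.2 elsewhere, dispersion 2) and RTS 1.0, against background genes at
  RTS 0.1.
* `simulate_epigenetic_matrix` — module prototypes spread with sd 3
  around a baseline breadth of 10 over 10 cell types, member genes
  jittered with sd 0.5 (a 6× separation), floored at zero.

These fixtures are deliberately idealised: no batch effects, no ambient
RNA contamination of the transcriptome, no doublet expression profiles,
no trajectory structure, and isotropic embedding geometry. Passing the
recovery suites demonstrates the algorithms' correctness and their
behaviour under controlled noise — not performance on real droplet data.

# Problem sizes and runtime choices

The test and acceptance workloads use 900-cell embeddings (3 × 300),
2,000-cell barcode matrices, 120-gene epigenetic matrices, and ≤ 100-cell
KDE/enumeration oracles — sizes at which the O(n²) KDE and DBSCAN paths
and exhaustive hypergeometric enumeration are exact and fast, and which
the simulations' recovery targets (3 peaks, ARI ≥ 0.95; k = 3, perfect
assignment) are calibrated to.

# Known limitations

* The KDE and DBSCAN paths materialise n × n distance kernels; beyond a
  few tens of thousands of cells a truncated-kernel implementation would
  be needed.
* Greedy barcode selection gives no maximality guarantee.
* The quantile-threshold demultiplexer's integer thresholds make its
  error rate step-wise in the fitted background mean.
* Peak membership is reported at the branch's birth level only.
* RTS derivation from epigenomic data, embedding computation, dataset
  integration, read-level processing and transcriptome-based doublet
  detection are all out of scope; their outputs are inputs here.
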