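---
title: "Methods behind gastrukit: quantifying micropatterned gastruloids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind gastrukit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gastrukit analyses BMP4-differentiated micropatterned human ESC colonies
("gastruloids"): 500 µm ECM discs on which hESCs differentiate within ~44 h
into concentric rings expressing SOX2 (ectoderm, center), T/Brachyury
(mesoderm), SOX17 (endoderm), and CDX2 (extraembryonic-like, edge), plus a
DAPI nuclear stain. The package covers the quantitative side of such a
study end to end: image-based quantification, single-cell transcriptomics,
cross-dataset label transfer with a randomization test, gene-module
scoring, and diffusion pseudotime — together with a synthetic-data module
that generates inputs with known ground truth so every stage is testable
without downloads.

This vignette explains the models and procedures, the parameters that
matter, the numerical choices, and what passing tests on synthetic data do
and do not establish about real data.

## Synthetic colonies and count matrices

`colony_spec()` + `simulate_colony()` draw cells ring by ring. A ring is an
annulus given as radius fractions of the colony radius; the default layout
is SOX2 in [0, 0.35], T in [0.35, 0.6], SOX17 in [0.6, 0.8], CDX2 in
[0.8, 1]. Default per-marker cell numbers (180/125/55/95) are proportioned
to the reported marker fractions (roughly 61% SOX2, 42% T, 18% SOX17, 32%
CDX2 of nuclei — summing over 100% because some cells co-express markers).
Co-expression rules make one cell a single centroid listed under both
markers, exactly how a co-expressing cell appears in an annotation table.
Because the true within-ring radial distribution of each cell type is not
known, it is a parameter: `"area-uniform"` (uniform over annulus area, the
default, what a homogeneous cell density implies) or `"radius-uniform"`.

Rendering is deliberately minimal: isotropic Gaussian intensity bumps
(`spot_sigma_px`, default 3 px at 2 µm/px) on a nonnegative noise floor.
There is no point-spread function, illumination field, or z-structure —
the images exercise blob detection and density mapping, not optics.

`count_sim_spec()` + `simulate_counts()` produce genes × cells integer
matrices from a gamma–Poisson (negative binomial) model: log-normal
per-gene baseline means, a multiplicative `marker_fold_change` for each
cluster's markers, per-cell library sizes drawn from a range (default
2,000–10,000), and a per-cell mitochondrial fraction (default 0.5–2.5%)
routed to `MT-`-prefixed genes. The default configuration mirrors the
study's scale: seven clusters (EPI-like, Ectoderm, Mesoderm-1/-2,
Endoderm, hPGCLC, ExE-like) totalling 2,475 cells with the canonical
marker panel, in a 2,000-gene universe kept deliberately smaller than a
full transcriptome so simulations stay fast; `n_genes` scales it up when
needed. Two niceties matter for testing: `exact_library_size` switches to
a gamma-weighted multinomial so column sums match the drawn library size
exactly, and `gene_mean_seed` fixes the gene-level baselines separately
from cell-level sampling, so a query dataset can be drawn from the same
gene-level distribution as a reference — which is what "a query drawn from
the reference's distributions" has to mean for label transfer to be
well-posed. The generator does not model doublets, ambient RNA, or
batch-specific gene detection; tests passing on it show the pipeline's
statistics are implemented correctly, not that they are robust to those
artifacts.

## Radial profiling

`radial_profile()` measures mean intensity in 20 equally spaced concentric
rings from the colony center to the colony radius. Two sampling modes
exist because plugin-style quantification samples pixels on each circle's
circumference, which is fragile on a pixel grid: the default
`"annulus"` mode averages over equal-width annuli (robust, and converging
to circle sampling as rings narrow), `"circle"` mode reproduces the
literal circumference sampling (pixels within half a pixel of the ring
radius). A ring with no pixels raises an error naming the ring rather than
returning NaN.

The colony center defaults to the centroid of an Otsu-thresholded DAPI
mask (`find_colony_center()`), overridable when centers are annotated.
Marker profiles are divided pointwise by the DAPI profile
(`normalize_to_dapi()`), expressing marker intensity relative to nuclear
density; `epsilon` defaults to 0 with an explicit error on an empty DAPI
ring, because silently producing infinities would corrupt averages.
`average_profiles()` reports per-ring mean and SEM = sd/sqrt(n) over
colonies; with a single colony SEM is reported as 0 with a warning so the
output stays well defined.

Pixel conventions are fixed once and used everywhere: 0-based coordinates,
x = column, y = row, pixel centers at integers.

## Density maps, counting, and the cosine overlap

A density map is a nonnegative grid whose entry is the expected number of
cells at that pixel; summing the map gives the expected cell count,
\(C = \sum_i \sum_j Y_{ij}\). `density_from_centroids()` builds the
annotation-derived map: each centroid deposits a Gaussian kernel
(default sigma 8 px, configurable — the width is a smoothing choice, not a
biological one) truncated at the grid boundary and renormalized to unit
mass, which makes `cell_count()` equal the centroid count exactly even for
edge cells. `detect_centroids()` is a deliberately simple local-maximum
blob detector (greedy non-maximum suppression by intensity) standing in
for learned density estimators, which are out of scope; it is adequate for
the synthetic spot images and clearly documented as such.

The spatial overlap of two populations is the cosine similarity of their
density maps,
\[
\mathrm{CosSim} = \frac{\sum_{ij} Y'_{ij} Y_{ij}}
 {\sqrt{\sum_{ij} Y'^2_{ij}}\sqrt{\sum_{ij} Y^2_{ij}}},
\]
ranging from 0 (disjoint) to 1 (identical distribution), symmetric, and
invariant to rescaling either map. An all-zero map is an error (the ratio
is undefined), not a 0. `simulate_sorting_layout()` produces the two
regimes this statistic is used to distinguish: `"mixed"` (both populations
uniform over the disc — the salt-and-pepper state just after reseeding
dissociated cells) and `"sorted"` (disjoint half-discs or patches — the
aggregated state after cell sorting). Mixed layouts score high, sorted
layouts near zero; the paired comparison over seeds is one of the
package's acceptance checks.

## Single-cell core

Quality control (`qc_filter()`) uses exclusive thresholds on detected
genes and mitochondrial fraction: a cell with *exactly* the minimum gene
count is removed. Replicate-specific thresholds are supported as a named
list; `gastruloid_qc_thresholds()` ships the gastruloid defaults (replicate
1: 200/7,500 genes, 3% mito; replicate 2: 200/6,000, 2.5%). QC columns are
recomputed from counts before filtering so stale metadata cannot change
the outcome, and a per-replicate pass/fail report is attached.

Normalization is counts-per-10,000 followed by log1p — the de facto
standard for droplet data. HVG selection ranks genes by
variance-to-mean dispersion z-scored within 20 equal-count
mean-expression bins and takes the top 2,000. `scale_regress()` removes
unwanted variation by per-gene linear regression on covariates
(mitochondrial fraction, total counts, and cell-cycle scores computed with
`module_score()` on the shipped, editable S/G2M gene lists), then
standardizes each gene and clips at ±10 so a few outlier cells cannot
dominate the embedding. Genes whose residual standard deviation is below
1e-8 are left at zero instead of having numerical noise inflated to unit
variance. The two replicates are processed jointly on shared HVGs with
replicate available as a regression covariate; full CCA anchor integration
is intentionally not reimplemented, and cross-replicate behavior is
validated property-style rather than against anchor internals.

Clustering builds a shared-nearest-neighbor graph (k = 20 neighbors,
Jaccard edge weights over neighbor sets including the cell itself, edges
below 1/15 pruned) and runs Louvain modularity optimization at resolution
0.4 — the convention this package adopts as its default — via igraph, on the first 15 principal
components. PCA signs are fixed (largest-magnitude loading positive) so
results are deterministic.

`find_markers()` is a one-vs-rest two-sided Wilcoxon rank-sum test on
log-normalized expression, vectorized with the normal approximation (tie
and continuity corrected; verified against `stats::wilcox.test` to 1e-10).
It reports the natural-log fold change of `mean(expm1(x)) + 1` ratios and
detection fractions, applies the 0.25 logFC / 25% detection filters before
testing, and Bonferroni-adjusts over all genes. Documenting the logFC base
matters: counts of "DE genes" are only interpretable given it.

## Label transfer and the randomization test

`shared_embedding()` harmonizes gene identifiers (case-insensitive symbol
match, or an explicit two-column orthology table for cross-species runs),
takes the reference's HVGs among shared genes, standardizes *both*
datasets with the reference's per-gene mean and sd, fits PCA on the
reference and projects both with its loadings. Using the reference's
moments for the query is essential: a query with skewed composition (say,
one cell type) would otherwise z-score its own markers to zero and land at
the reference origin. This projection + weighted kNN voting replaces
anchor-based transfer; the computation the original description actually
states — scores from the labels of a cell's nearest reference neighbors —
is preserved, while anchor internals are not reproduced.

`transfer_labels()` scores each reference label by the weighted fraction
of the query cell's k nearest reference neighbors carrying it (Gaussian
weights with per-cell bandwidth equal to the k-th neighbor distance by
default; uniform optional; k defaults to 30, a common choice with no
canonical value). Rows sum to 1. `assign_predicted()` takes
the row argmax, breaking exact ties toward the lexicographically first
label and flagging them.

`composition()` tabulates per-cluster fractions of predicted labels —
the statistic the randomization test resamples. For each cluster *i* of
size *n_i*, `permutation_significance()` draws B = 1000 resamples of
*n_i* cells with replacement from **all** query cells, computes the label
composition of each, and reports
\(p_{ij} = (\#\{k: Perc_{ijk} \ge Perc_{ij}\} + 1)/(B + 1)\): the
comparison is inclusive and the pseudo-count keeps p off zero, so p lies
in [1/(B+1), 1]. No multiple-testing correction is applied (significance
is called at alpha = 0.05 per pair by design), and the
result records that. One seed drives the entire resample stream; clusters
are processed in order of first appearance in the cell sequence. First
appearance, not sorted label order, is the deliberate choice: it makes the
p-value matrix exactly permutation-equivariant under cluster renaming
(sorting by label would change the draw order, and therefore the
p-values, when clusters are renamed), which is an invariant the test suite
checks exactly against a brute-force oracle.

`spearman_cluster_correlation()` compares datasets at cluster level:
average log-normalized expression per cluster on a shared feature list
(typically the top shared HVGs), then Spearman rank correlation for every
cluster pair — invariant to monotone transforms, with constant average
profiles flagged as NA rather than silently zero.

## Module scores, diffusion maps, pseudotime

`module_score()` implements the expression-matched control design: genes
are cut into 24 equal-count bins of mean expression; each set gene draws
100 controls from its own bin; the score is mean(set) − mean(controls) per
cell. The PGC signature (NANOS3, SOX17, TFAP2C, PRDM1, NANOG) ships in
`inst/extdata/gene_sets.json` alongside editable cell-cycle lists. The
score is unbiased for a random gene set — its average over many random
sets is near zero — but an individual random set that happens to include a
gene from the top expression bin can sit visibly off zero, because wide
bins make controls an imperfect match there; that is a property of the
binned-control design itself, shared with the standard implementation.

`diffusion_map()` follows the standard density-normalized diffusion-map
construction: a symmetric kNN-union graph (knn = 40), Gaussian
kernel with global width sigma = 8, density normalization (dividing the
kernel by the product of row sums, removing sampling-density bias), and
row-normalization into a cell-to-cell transition matrix. Eigenpairs come
from the symmetric conjugate matrix; the trivial eigenvalue-1/constant
pair is dropped from the returned components. Sigma is taken as an input
— the upstream package's automatic sigma estimation is not reproduced. A
disconnected graph triggers a warning: eigenvalue 1 is then repeated and
the leading components become blockwise-constant component indicators,
which the tests account for. `cluster_transitions()` averages each
cluster's total transition probability into every other cluster and
renormalizes rows, giving the cluster-to-cluster transition heatmap.

`pseudotime_pbfs()` converts graph distance from a root population into a
pseudotime by repeated stochastic floods: each of `n_sims` (default 100)
simulations seeds a random 80% of the roots, repeatedly admits a random
80% of the frontier's unvisited neighbors, and records each cell's first
visit step normalized by the simulation's depth; the final value is the
mean over simulations rescaled to [0, 1] with roots pinned at 0. The
fractions and simulation count are exposed configuration, because the
cited method's internals (visit-frequency thresholds and the exact
step-to-pseudotime conversion) are not restated in the source; this
normalization is a documented stand-in that preserves the ordering
behavior — on a planted 1-D trajectory the rank correlation with true
position exceeds 0.9, and on a planted EPI → Mesoderm-1 → Mesoderm-2
lineage the median pseudotimes order correctly. Roots default naturally to
all cells of a named cluster (the EPI-like cluster in the motivating
analysis); no root-selection rule is inferred beyond that. Unreachable
cells get NA and a warning rather than an arbitrary value.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run entirely on synthetic data
at sizes chosen to keep a full run in minutes on one CPU: recovery suites
use 7 × 60 cells × 2,000 genes (clustering ARI ≥ 0.95, marker recovery
≥ 95% with zero false positives on null data), the permutation-test
calibration uses 2,000 shuffled-label datasets of 50 cells at B = 199
(the B = 1000 configuration is separately verified exactly against a
brute-force oracle), and the sorting comparison uses 20 paired seeds.
Every stochastic step takes an explicit seed, and fixed seeds give
bit-identical outputs — including the permutation resample stream and the
pseudotime floods.

## Known limitations

No optics or read-level simulation; no doublet/ambient-RNA modeling; no
anchor-based integration or reciprocal PCA; no RNA velocity or branch
assignment; blob detection is intensity-based and will undercount dense
overlapping nuclei in real images; exact nearest-neighbor search and
dense eigendecomposition bound practical sizes to a few thousand cells,
which covers the study scale this package targets.
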