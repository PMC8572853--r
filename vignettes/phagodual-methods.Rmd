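---
title: "Methods: signature scoring and dual-feature phagocyte detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring and dual-feature phagocyte detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`phagodual` re-implements, as a tested and reusable pipeline, the
quantitative core of a two-condition (normal vs inflamed middle-ear mucosa)
single-cell RNA-seq analysis: per-cell quality control, total-count log
normalization, highly variable gene (HVG) selection, PCA, graph clustering,
Wilcoxon marker detection, gene-signature scoring against expression-binned
random controls (the *Cell Score*), dual-feature (non-professional
phagocyte) cell calling, condition-wise composition comparison, and a
permutation-based ligand-receptor screen. A synthetic count generator with
planted ground truth is a first-class module: every downstream claim the
package makes is validated against data whose truth is known by
construction.

# The Cell Score

For a target gene set $G_t$ and a cell $c$, the Cell Score is

$$\mathrm{CS}(c) \;=\; \frac{1}{|G_t|}\sum_{g \in G_t} x_{gc}
\;-\; \frac{1}{|G_c|}\sum_{g \in G_c} x_{gc},$$

where $x$ is log total-count-normalized expression and $G_c$ is a pooled
control multiset: all genes are partitioned into `n_bins = 25` bins of
near-equal size by rank of mean expression across all cells, and for each
target gene `n_ctrl = 100` control genes are drawn uniformly *without
replacement* from the target's bin, *excluding all signature genes*. The
pooled multiset keeps multiplicity (a gene drawn for two targets counts
twice). Controls are drawn once per `(signature, seed)`, not per cell; in
`score_many()` each signature uses its own deterministic substream of the
seed, so scoring signatures together or alone gives identical columns.

Choices the originating description leaves open, fixed here:

* **Bins** are equal-size rank bins (not equal-width expression intervals);
  when the gene count is not divisible by 25, the remainder genes go one
  each to the *lowest* bins — an arbitrary but fixed, documented rule.
* **Controls** exclude signature genes and are drawn without replacement,
  preventing self-matching inflation.
* **"Relative expression"** is the log normalized layer
  ($\ln(1 + 10^4 \cdot \text{count}/\text{total})$); no per-gene centering
  is applied before averaging.

Exactness properties: with `n_ctrl` at least the bin size the draw is
forced, and `score_cells()` agrees with a direct mean-difference computation
to $10^{-12}$; adding a constant to every gene of a cell leaves that cell's
score unchanged; identical `(matrix, signature, seed)` give bit-identical
scores.

**Null-calibration caveat.** The across-cell *mean* CS of a random signature
is not a mean of independent per-cell quantities: given a control draw, it
equals the mean over targets of (target mean expression − mean of its
sampled bin-mates). This control-matching residual has standard deviation of
order (within-bin spread of gene means)/$\sqrt{|G_t|}$ and does not shrink
with the number of cells. With a realistic heavy-tailed baseline the top
expression bins are wide, so on null data the mean CS, while small in
absolute terms (|mean| ≤ 0.05 is asserted in the test suite at
$|G_t| = 50$), can exceed several *per-cell* standard errors. Per-cell SEs
understate the variability of the mean score; uncertainty statements about
mean scores should come from control re-draws or replicate seeds.

# The synthetic generator

The generator emulates the structure of the modelled experiment, not any particular dataset. Counts are
gamma-Poisson (negative binomial) with gene-shared dispersion 0.3 around
$\mu_{gc} = p_{g(\text{type})} \cdot L_c$: a per-type expression profile
times a log-normal library size ($\log L \sim \mathcal{N}(\log 2500,
0.35^2)$). Profiles are a shared lognormal gene baseline (sdlog 1.2) times
program multipliers, renormalized to sum to one so that expected total
counts are independent of cell type (composition effects are not confounded
with depth). Eight cell types carry disjoint 50-gene marker programs at
$2^2$-fold elevation; professional phagocytes (neutrophils, macrophages,
dendritic cells) additionally carry a 40-gene phagocytosis program at
$2^1$-fold; macrophages carry an M2 polarization program. Composition per
condition mirrors the modelled tissue: epithelial + fibroblast ≈ 2/3 of normal mucosa;
neutrophil + macrophage dominate the inflamed mucosa. A 10-gene `Mt-` block
is tuned to an expected 5% mitochondrial fraction.

**Dual-feature cells.** Three populations are planted (5% of their host
type): proliferation×phagocytosis and epithelial×phagocytosis inside
epithelial cells, osteoblastic×phagocytosis inside fibroblasts. Planting is
multiplicative on *both* programs (each raised to at least $2^2$-fold, a
max rule so a program already active in the host is not double-counted), so
planted cells genuinely co-express both programs — the signature of a
non-professional phagocyte rather than of a doublet.

**Doublets.** 5% of barcodes are doublets: two random parents' counts are
summed and binomially thinned to a fresh draw from the library-size law
scaled by `doublet_depth_factor = 1.6`. The factor models the empirically
deeper libraries of real doublets and is essential: thinning the sum of two
cells to exactly the singlet depth law is, by the Poisson thinning identity,
statistically indistinguishable from a singlet in every depth statistic, and
would leave nothing for depth-based filters to catch. Even at 1.6×, the
feature-count heuristic (`flag_doublets_heuristic()`, flag when
`n_features > median + k·MAD` within condition) is deliberately weak: at
`k = 2` it attains roughly 0.19 recall at 0.017 false-positive rate on the
default generator. Its role in this package is the *separation* property —
planted doublets are flagged at a clearly higher rate than planted
dual-feature cells, because depth, not co-expression, drives the flag — not
high-recall doublet removal, for which dedicated profile-based tools exist.
On synthetic data the truth labels can be used instead.

What the generator does **not** emulate: batch effects between replicate
samples, ambient RNA, cell-cycle structure outside the proliferation
program, UMI saturation, or read-level noise. Tests passing on this
substrate validate the pipeline's statistical machinery, not its robustness
to those real-data artefacts.

# QC, normalization, HVG, PCA

QC statistics are `n_features` (genes with count > 0), `total_counts`, and
the mitochondrial fraction (prefix `Mt-`, case-insensitive, configurable; an
all-zero cell has fraction 0 and is flagged). The shipped per-condition presets are: inflamed keeps 200 ≤ features ≤ 4000 and mito ≤ 20%; normal
keeps 200 ≤ features ≤ 3000 and mito ≤ 40%. Removal inequalities are
*strict* as printed, so boundary cells are kept; the removal report
attributes each removed cell to one reason with precedence low-features →
high-features → mito (this affects only the report, never the removed set).
Filtering is idempotent.

Normalization is $\ln(1 + 10^4\,c_{gc}/\sum_g c_{gc})$, preserving the zero
pattern; the raw counts are carried alongside. HVGs are ranked by
standardized variance — observed variance over the value expected at the
gene's mean from a loess fit ($\log_{10}$ var vs $\log_{10}$ mean, span 0.3,
with a Poisson-like mean fallback if the fit degenerates) — with ties broken
by gene id. PCA z-scores each selected gene, clips z at ±10 to bound
outlier leverage, and fixes each component's sign by making its
largest-magnitude loading positive, so the embedding is deterministic.

# Clustering and markers

Cells are clustered on a k-nearest-neighbour graph (Euclidean in PC space,
`k = 20`) by Louvain modularity optimization at `resolution = 0.6`, seeded
and therefore reproducible; labels `C0, C1, ...` are ordered by decreasing
size. The marker test is one-vs-rest Wilcoxon rank-sum per gene. The
implementation is vectorised over genes and uses the exact rank-sum null
when a gene has no ties and both groups have fewer than 50 cells (the
classical switch), otherwise the tie-corrected normal approximation with
continuity correction; the exact branch is what lets the test agree with
exhaustive enumeration to numerical precision at small group sizes, where a
pure normal approximation provably errs by up to ~0.04 in p. Real sparse
expression always contains ties, so the normal path is the one exercised at
scale. Fold changes are $\log_2((m_{in}+1)/(m_{out}+1))$ on de-logged
(`expm1`) means; Benjamini-Hochberg adjustment is applied across genes
*within* each cluster (each cluster's marker list is its own family); the
significance filter keeps adjusted p < 0.05 AND $|\log_2 FC| > 2$, both
strict.

# Dual-feature calling and composition

The headline analysis extracts `Cd68`-positive cells (raw count ≥ 1 by
default; the threshold is configurable), drops heuristically flagged doublets, and scores the phagocytosis
signature against each candidate lineage signature. A cell is called
dual-feature when *both* scores are strictly above their thresholds;
thresholds default to each score's within-dataset 75th percentile — an
explicit, tunable replacement for by-eye score-scatter inspection.
Correlations between paired scores are Pearson with the t-transform p;
two-group score comparisons are Wilcoxon. Composition tables are
within-condition fractions (summing to one per condition) with unlabeled
cells under an explicit `unassigned` row.

# Ligand-receptor screen

The screen deliberately simplifies a full communication model to its
implementable, stated elements: for every (pair, sender, receiver) the score
is mean ligand expression in the sender times mean receptor expression in
the receiver; a record is valid only when both cluster means reach 0.2 (the
cutoff is applied to cluster-mean normalized expression — the statistic the
source leaves unspecified — and is configurable). Significance is by global
label permutation with the add-one estimator
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$, so
$p \in [1/(n_{perm}+1), 1]$; BH adjustment runs across valid records. The
bundled pair fixture contains six interactions central to the modelled
inflammation system (Csf1–Csf1r, Il34–Csf1r, Ccl3–Ccr5, Cxcl1–Cxcr2, Il1b–Il1r2,
Igf1–Igf1r), all present in the synthetic catalogue with the expected
sender/receiver placement.

# Pipeline and provenance

`run_pipeline()` executes simulate → qc → normalize → hvg_pca → cluster →
markers → score → dualfeature → lrscreen, writing text intermediates (MTX +
CSV) and a manifest of MD5 digests. A stage is skipped when its recorded
input and output digests are unchanged; corrupting an intermediate reruns
its producing stage (and, if the repaired file differs, its dependents).
Every stage seeds from a named substream of one global seed, so adding a
stage never perturbs another stage's draws and two runs with the same
configuration and seed are bit-identical (no timestamps are written). CSV
headers record the seed and a configuration hash as comment lines.

# Problem sizes and determinism in the test suite

The shipped tests run the generator at 200–500 cells per condition and
800–2000 genes, sizes at which every distributional check is already stable;
the end-to-end dual-feature recovery uses the full default configuration
(2000 genes, 900 + 1200 cells) over ten seeds, and the determinism check
runs the whole pipeline twice at 800 genes / 450 cells. All randomness flows
through explicit seeds; there are no skipped or environment-conditional
tests.

# Known limitations

* The Cell Score's mean over cells carries the control-matching residual
  described above; compare scores between cell groups rather than testing a
  single mean against zero with per-cell standard errors.
* The marker log-fold-change uses pseudocount-1 de-logged means, which
  compresses fold changes for genes with small normalized means; the
  |log2FC| > 2 filter is therefore conservative on lowly expressed markers.
* The LR screen's product-of-means score ignores multi-subunit receptors,
  mass-action kinetics and pathway aggregation.
* The doublet heuristic keys on library depth only; it is a guard for the
  dual-feature analysis, not a general doublet remover.
* Conditions are analyzed jointly by concatenation; no batch/anchor
  integration is performed.
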