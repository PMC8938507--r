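---
title: "Methods: models, scores and statistics in regensc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, scores and statistics in regensc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regensc)
```

`regensc` is a pipeline for plate-based (CEL-seq2-style) single-cell RNA-seq
studies of intestinal crypt regeneration: it takes paired FASTQ or UMI count
matrices to clusters, per-cell gene-signature scores, stemness scores,
differential expression and group-comparison statistics. Every stage is
exercised against a synthetic-data generator with known ground truth, so the
whole chain is testable without any external download. This vignette explains
the models and conventions behind each stage, the tunable parameters, and the
design choices made where the underlying methodology leaves them open.

## The count simulator

`simulate_counts()` draws UMI counts for gene $g$ in cell $c$ of cell type
$t$ from a negative binomial,

$$
  K_{gc} \sim \mathrm{NB}\!\left(\mu_{gc},\ \theta\right),
  \qquad
  \mu_{gc} = L_c \, b_{g}(r_c) \, \mu_{gt} \, f^{\,[g \in S,\ c \text{ targeted}]},
$$

with variance $\mu + \mu^2/\theta$. Here $L_c$ is a log-normal library size
(`libsize_meanlog`, `libsize_sdlog`; default median 5,000 UMIs, sdlog 0.3 —
typical totals for plate-based UMI libraries), $b_g(r)$ a per-gene log-normal
batch factor for replicate $r$ (`batch_sdlog`, default 0.1, mean-corrected so
$E[b] = 1$), $\mu_{gt}$ the relative expression of gene $g$ in type $t$
(columns normalized to sum to 1), and $f \ge 1$ the planted fold effect of a
gene signature $S$ in targeted cells ($f = 1$ plants nothing). The default
inverse-dispersion $\theta = 10$ reflects the moderate overdispersion of
UMI-collapsed counts; $\theta \to \infty$ with fixed library sizes recovers
the Poisson limit, which the tests verify as a moment check.

`default_sim_config()` emulates the study design the package targets: two
conditions (normal vs. post-injury) × two reporter gates (Venus$^+$ /
Venus$^-$) × two replicates, at 1/8 of the sorted-cell scale
(30/60 normal $+/-$ and 36/72 injured $+/-$ cells per replicate, 396 cells
total, 500 genes). Five cell-type programs are planted — stem, progenitor,
enterocyte, secretory, revival — each with a 40-gene marker block at 8-fold
elevation. Reporter-positive gates are enriched for the secretory lineage,
and revival cells appear only after injury, mirroring the biology of
injury-induced facultative stem cells. The per-condition type proportions
(e.g. 70% secretory in the normal Venus$^+$ gate, 40% revival in the injured
Venus$^+$ gate) are declared defaults: cluster-level compositions are not
published as exact proportions, so these were chosen once as plausible for
FACS-gated crypt cells and are not tuned. Fetal-intestine and adult-stomach
signatures (25 genes each) plus a smaller revival-stem-cell signature are
planted at `effect_fold` (default 4) in revival cells; 5% of genes are
flagged mitochondrial with elevated shared expression to exercise the
mitochondrial QC filter.

What the generator deliberately does **not** emulate: sequencing errors,
doublets, ambient RNA, gene-length effects, and continuous differentiation
trajectories (types are discrete). Passing tests therefore demonstrate
correctness of the computational chain under a faithful-but-clean data model,
not robustness to every artefact of real libraries.

`simulate_fastq()` emits each counted molecule as a read pair
(`reads_per_molecule` copies): read 1 is the 6-nt UMI, then the 6-nt cell
barcode, padded with `A` to 25 nt; read 2 is a random 75-nt substring of the
gene's transcript. UMIs are drawn without replacement within each (cell,
gene), so UMI-collapsed counting reproduces the input matrix exactly — the
round-trip oracle used in the tests. The synthetic transcriptome
(`make_transcriptome()`) enforces at generation that no 75-mer occurs in two
genes, making exact-substring assignment unambiguous. A design is restricted
to one plate (≤ 96 cells, distinct wells) for FASTQ emission.

## Demultiplexing and counting

`demultiplex()` matches the barcode field against the plate layout; the
default is exact matching (`max_mismatch = 0`). One-mismatch correction is
opt-in and allowed only when the layout's pairwise barcode Hamming distance
is at least $2m + 1$ — the coding-theory condition under which correction is
unambiguous — and `barcode_layout()` generates barcode sets satisfying a
requested minimum distance. `assign_gene()` replaces genome alignment with
exact-substring lookup against the transcriptome: appropriate here because
simulated reads are error-free and the transcriptome is built to be
read-length-distinguishable; reads matching no gene or more than one gene are
discarded with reasons (`no_gene`, `ambiguous_gene`). Counting collapses
records to distinct (cell, gene, UMI) triples, so it is idempotent under
duplicated reads and invariant to read order; the processing report keeps
raw-read accounting (total = assigned + discarded by reason).

## Quality control, normalization, variable genes, PCA, batch adjustment

- **QC** (`qc_filter()`): cells with fewer than 200 or more than 5,000
  detected genes are discarded — the boundaries themselves are kept, reading
  the discard rule as strict inequalities — and optionally cells whose
  mitochondrial UMI fraction exceeds 0.10 (again: exactly 10% is kept).
  Genes are never removed.
- **Normalization** (`normalize_log()`):
  $y_{gc} = \log\!\left(1 + 10^4 \, K_{gc} / \sum_g K_{gc}\right)$, natural
  log. This is the de-facto standard global-scaling transform of the
  single-cell toolchains this pipeline mirrors; the scale factor and
  transform are recorded in the object's provenance. Zeros map to zeros and
  within-cell ranks are preserved.
- **Variable genes** (`find_variable_genes()`): per gene, the mean $m_g$ and
  variance of the back-transformed expression $\mathrm{expm1}(y)$ give a
  dispersion $d_g = \log(\mathrm{var}/\mathrm{mean})$; genes are cut into 20
  equal-width bins of $m_g$ and $d_g$ is z-scored within each bin (a bin with
  fewer than two finite dispersions keeps $z = 0$, since no standardization
  is possible). Selection requires $m_g > 0.5$ and $z_g > 0.5$ — the
  mean-variance-plot convention these cutoff values presume.
- **Scaling and PCA** (`scale_and_pca()`): selected genes are z-scored
  across cells, clipped to $\pm 10$, and the cells projected on the leading
  principal components (default 20; 15 are used downstream for the
  two-replicate design). Since rows are centered by construction, the PCA is
  computed as the SVD of the scaled matrix, so reconstruction from all
  components returns it exactly — a property the tests assert. Component
  signs are fixed by making each component's largest-magnitude loading
  positive, giving bit-reproducible output. Zero-variance genes are dropped
  with a warning.
- **Batch adjustment** (`batch_adjust()`): per component, each replicate's
  centroid is subtracted and the global centroid restored. This centroid
  alignment is a deliberately simple, exactly testable adjustment (it
  preserves within-batch geometry and removes any constant batch offset); it
  is adequate when batches share cell-type composition, as replicate designs
  intend, and is not an iterative mixture-aware integration. The number of
  dimensions carried forward is configurable (15 or 20 in the intended
  designs).

## Neighbor graph, clustering, embedding, annotation

`build_snn_graph()` computes exact Euclidean $k$-nearest neighbors (default
$k = 20$) from the full distance matrix — at the few-hundred to few-thousand
cell scale this is cheap and lets ties at the $k$-th distance break
deterministically by lowest cell index. Each cell's neighbor set includes
itself; edge weights are the Jaccard overlap of neighbor sets, pruned below
$1/15$. Louvain modularity optimization (`cluster_louvain()`, resolution
default 0.8, seeded) partitions the graph; resolution and prune threshold
are the common toolchain defaults, as the methodology being mirrored states
neither. Cluster counts are data-dependent and are not treated as a
reproduction target. `embed_tsne()` provides a seeded t-SNE for
visualization only — no quantitative result depends on embedding
coordinates. `annotate_clusters()` labels each cluster by the signature with
the highest cluster-mean score; an exact tie, or a top-2 margin below
`min_margin`, yields `"unresolved"`.

## The min-max signature score

For a gene set $S$ present in the matrix, each gene's log-normalized vector
is min-max scaled across cells,
$z_{gc} = (y_{gc} - \min_c y_g)/(\max_c y_g - \min_c y_g)$, so every gene
spans the same dynamic range (0 to 1); a constant gene contributes 0 by
convention. The raw score is the per-cell mean over signature genes,
$S_c = \frac{1}{|S|}\sum_{g \in S} z_{gc} \in [0, 1]$. Because $y$ tracks
absolute transcript abundance, the displayed score rescales by the average
per-gene maximum, $H_c = S_c \cdot \overline{\max_c y_g}$, so its dynamic
range corresponds to the average absolute amount of the signature's
transcripts — the quantity painted on embedding heat maps. Signature genes
absent from the matrix are dropped (not zero-filled) and the retained
fraction recorded; scoring a signature with no present genes is an error.
Note one degenerate consequence of the constant-gene convention: on a
one-cell matrix every gene is constant, so $S \equiv 0$ and $H \equiv 0$.

Cell-cycle phase calling (`cell_cycle_phase()`) is a declared
simplification: the S and G2M gene sets are scored as above, each score is
centered across cells, and the phase is the larger centered score, with
`G1/G0` when both are at or below the threshold (default 0). No
control-gene bins are used.

## Transcriptional-diversity stemness score

`stemness_score()` follows the transcriptional-diversity principle — less
differentiated cells express detectably more genes — in a simplified,
fully specified form: the detected-gene count $D_c$ is correlated with each
gene's expression ($r_g$, Pearson); the gene-count signature $GCS_c$ is the
mean expression of the `top_m` (default 200) most $D$-correlated genes; the
signature is smoothed over the SNN graph by the damped diffusion
$s \leftarrow (1-\alpha)\,GCS + \alpha\, W s$ ($W$ row-normalized SNN
weights, $\alpha = 0.5$, 30 iterations — enough for convergence at these
graph sizes; isolated cells keep their own value); the final score is the
rank-normalization of $s$ to $[0, 1]$. The diffusion replaces the original
method's regression-plus-Markov machinery; consequently only the *ordering*
of scores is meaningful, and all tests and acceptance checks are
ordering-based (median separation, Spearman correlation with planted
diversity), never value-based. With $\alpha = 0$ the score is exactly the
rank-normalized raw $GCS$, a limit the tests pin down. If all cells have
identical diversity the score is degenerate and set to 0.5 with a warning.

## Differential expression

Marker finding (`find_markers()`) and grouped comparisons
(`find_degs_grouped()`, e.g. a "regenerating" cluster group versus all other
cells) use the two-sided Wilcoxon rank-sum test per gene — the standard
default for single-cell marker detection — with midranks, tie-corrected
variance and continuity correction on the normal-approximation path, and
exact enumeration for tiny tie-free samples (≤ 12 values). Genes are
pre-filtered by detection fraction (`min_pct` 0.1 in either group) and
absolute log2 fold change (0.25), computed as
$\log_2\!\big[(\mathrm{mean}\,\mathrm{expm1}(a) + 1) /
(\mathrm{mean}\,\mathrm{expm1}(b) + 1)\big]$ — back-transformed group means
with a pseudocount, the convention matching the filters' scale. P-values are
Bonferroni-adjusted over the genes actually tested; records are ranked by
raw p, then $|\mathrm{log2FC}|$, then gene id for determinism. Volcano
rankings use the raw p-value (both raw and adjusted are reported), and the
top-$n$ set (default 100) is flagged rather than truncated.

## Group-comparison statistics

- `t_test_two_tailed()`: classical pooled two-sample t (Welch optional);
  zero-variance degenerate inputs return p = 1 (equal means) or a flagged
  p = 0. `summarize_mean_sem()` gives the mean ± SEM summaries used in
  figures.
- `steel_dwass()`: for each pair of groups the combined sample is midranked
  and the rank sum standardized with the exact tie-corrected variance (no
  continuity correction); the familywise p refers $|t|\sqrt{2}$ to the
  studentized-range distribution with $k$ groups and infinite df. At
  $k = 2$ this reduces exactly to the uncorrected two-sided
  normal-approximation Wilcoxon test. The studentized-range CDF is base R's
  `ptukey`; an independent quadrature of the range integral serves as the
  oracle in the tests. Finite-sample accuracy: at $n = 4$ per group the rank
  statistic has only ~17 support points and the asymptotic p deviates from
  the exhaustive permutation distribution by up to ~0.08 for mid-range
  p-values (the far tail agrees to ~0.02); the test suite documents this
  measured accuracy. With realistic group sizes (dozens of cells and more)
  the approximation is the standard one.
- `tukey_kramer()`: pooled within-group variance from one-way ANOVA;
  pairwise $q = |\bar x_i - \bar x_j| / \sqrt{(s^2/2)(1/n_i + 1/n_j)}$
  referred to the studentized range with $N - k$ df. At $k = 2$ it equals
  the pooled t-test exactly ($q = |t|\sqrt 2$).
- `crypt_positive_fraction()`: a crypt is marker-positive when it contains
  at least `min_cells` (default 3, inclusive) marker-positive cells; the
  per-animal fraction of positive crypts is the unit fed to
  `tukey_kramer()` across treatment groups (the intended design: 4 animals
  × 200 crypts per condition).

When per-cell scores are compared across conditions, cells are pooled across
animals as the sampling units — the convention implied by per-cell group
sizes in such comparisons — and this is a known limitation: it ignores
animal-level nesting.

## Problem sizes, determinism and degenerate inputs

The test and verification workloads use the generator's default scale (396
cells × 500 genes; a 96-cell plate at ~10$^5$ reads for the FASTQ round
trip; 5 clustering seeds; 1,000 null replicates for type-I calibration; 200
replicate crypt experiments for familywise calibration) — sizes chosen so
the full chain, including its brute-force oracles, verifies in well under a
half hour on one core while leaving each check statistically decisive. All
stochastic steps take explicit integer seeds, and every stage is
deterministic given its seed (fixed kNN tie-breaks, fixed PCA sign
convention, seeded Louvain and t-SNE). Degenerate inputs have defined
behaviour rather than incidental output: constant genes score 0, a
single-batch adjustment is the identity, all-identical cells are rejected by
the embedding and give stemness 0.5 with a warning, all-tied samples give
p = 1, and zero-variance ANOVA pairs are flagged.

## Known limitations

The exact-substring gene assignment, centroid batch adjustment, simplified
cell-cycle caller and diffusion-based stemness score are deliberate,
documented simplifications of their production counterparts (aligners,
iterative integration, control-bin scoring, the original
transcriptional-diversity implementation). They keep every stage exactly
specifiable and testable, at the cost of not modelling alignment ambiguity,
nonlinear batch structure, or the original methods' numerical details. The
simulator's discrete cell types make cluster recovery easier than in real
crypt data, where differentiation is continuous; recovery results on
synthetic data bound what the pipeline can do under its own model, not on
arbitrary real libraries.
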