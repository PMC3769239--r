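---
title: "Pooled cross-platform meta-analysis of endothelial expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled cross-platform meta-analysis of endothelial expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmark)
```

## The problem and the model

Blood endothelial cells (BEC) and lymphatic endothelial cells (LEC) are
distinguished in practice by a handful of marker genes, yet single-study
microarray comparisons of the two cell types overlap poorly with one
another. Pooling profiles from many laboratories and several array
platforms increases biological variability on purpose: a gene that stays
differential across donors, vascular beds and platforms is a far better
marker candidate than one found in a single experiment. The cost is that
platforms differ in gene coverage and per-gene intensity scale, so the
pooled matrix must be harmonized before any testing.

`vesselmark` models the pooled matrix as log2 intensities $x_{gs}$ for gene
$g$ in sample $s$, with explicit missingness of two kinds: *structural*
(the gene has no probe on the sample's platform) and *sporadic* (the value
did not survive preprocessing). The processing chain is:

1. **Merge** per-platform matrices on canonical gene ids; multiple probes
   mapping to one gene collapse to their per-sample mean.
2. **Filter**: keep genes observed in at least 40% of all samples. The
   boundary is inclusive — 4 observed values out of 10 samples survive —
   and the fraction is evaluated on the combined matrix, after merging.
3. **Standardize** each gene over its observed values across *all* samples
   from all platforms at once:
   $z_{gs} = (x_{gs} - \mathrm{median}_g)\, /\, \mathrm{sd}_g$.
   A per-gene additive platform shift moves the median with it, so
   median-centering absorbs shared location offsets; SD division equalizes
   per-gene scale between platforms.
4. **Test** BEC vs LEC per gene with the Welch unequal-variance two-tailed
   t-test, and compute the log2 fold change as a difference of group means.
5. **Correct** for multiplicity with robust FDR estimation:
   $\hat\pi_0 = \min(1,\, 2\bar p)$, and step-up q-values
   $q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j$ clipped to 1.
   Under a uniform null $\mathbb{E}[2\bar p] = 1$, so $\hat\pi_0$ estimates
   the fraction of truly null genes and rescales the Benjamini–Hochberg
   step-up quantity; with $\hat\pi_0 = 1$ the procedure reduces to plain
   BH, which is exposed as an option.
6. **Call** a gene vessel-type specific when $|{\log_2 \mathrm{fc}}| \ge 1$
   (fold change $\ge 2$) and $q \le 0.05$, both inclusive.
7. **Compare** marker sets across analyses by exact Venn partition, and
   **embed** samples by classical multidimensional scaling of Euclidean
   distances.

## Which matrix feeds which stage

The fold-change threshold "$\ge$ 2-fold" is meaningful on log2 intensity
units, not on median/SD-standardized scores, where a per-gene division by
the SD destroys the unit. The pipeline therefore computes *both* matrices
and feeds the merged-but-unstandardized log2 matrix to the differential
stage (test and fold change on the same values), while the standardized
matrix is produced as the harmonized artifact for inspection and export.
For the MDS stage the merged log2 matrix is likewise used: the embedding is
meant to show overall expression relatedness of samples, including the
platform- and tissue-level structure that standardization deliberately
removes. Which matrix entered a run is visible in the run manifest.

The test itself is the Welch t-test because that is the study's stated
statistic for group comparisons; no moderated-variance (limma-style)
shrinkage is applied — the contrast is a plain two-group comparison with
dozens of samples per group, where gene-wise variance estimates are stable.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `minFrac` | 0.40 | fraction of samples | minimum observed fraction per gene; inclusive |
| `fcThreshold` | 2 | fold | marker call, $|\log_2\mathrm{fc}| \ge \log_2(\mathrm{fc})$ |
| `qThreshold` | 0.05 | probability | robust-FDR q cut-off, inclusive |
| `k` | 3 | dimensions | MDS output dimensionality (3-D visualisation) |
| `collapse` | mean | — | multi-probe collapse; `max`/`first` available |

## The synthetic data generator

`simulateExpression()` is a first-class module, not a test shim: it
emulates the statistical structure of the pooled public data so that every
downstream stage is testable offline. The generative model, seeded and
fully reproducible:

* per-gene baseline $b_g \sim N(\mu_b, \sigma_b^2)$ (defaults 6 and 2 on
  the log2 scale, the typical range of GC-RMA summaries);
* planted markers: BEC markers at $b_g \pm \mathrm{effect}/2$ in BEC/LEC
  samples, LEC markers mirrored — symmetric planting makes "BEC-specific"
  and "LEC-specific" exact mirror cases so direction calling is testable
  both ways;
* hybrid cell lines (HMEC1, TIME): the convex mixture
  $\lambda \cdot \mathrm{BEC} + (1-\lambda)\cdot\mathrm{LEC}$ mean
  ($\lambda = 0.5$) plus a $+2$ log2 shift on 200 line-specific drift
  genes. This is the minimal mechanism that reproduces the qualitative
  observation that immortalized lines cluster *near to, but not among*,
  primary endothelial cells: the mixture places them between the BEC and
  LEC centroids, the drift genes push them off the segment;
* a CONTROL outgroup (prostate-like tissue) with an independent per-gene
  $N(0, 1.5^2)$ divergence — genome-wide and larger than the marker
  effects, so the outgroup is far from every endothelial cluster. The
  magnitude is the generator's own choice (no published estimate exists);
  it only needs to dominate the within-endothelium differences;
* per-gene per-platform offsets $N(0, 0.5^2)$ — the batch structure the
  harmonization step exists to remove;
* observation noise $N(0, 0.5^2)$, a realistic residual SD for log2 array
  data;
* per-platform gene coverage (1.0 / 0.6 / 0.9 for GPL570 / GPL571 /
  GPL5188, reflecting the smaller U133A array) drawn as a seeded random
  subset — structural missingness; plus 2% MCAR dropout — sporadic
  missingness. The two mechanisms are kept distinct because the 40% filter
  must see both.

The default design (`defaultPaperlikeConfig()`) reproduces the pooled
study's sample layout: 14 BEC + 10 LEC on GPL570 (the 24-sample restricted
Dataset A), 9 + 2 on GPL571, 10 + 2 on GPL5188 — 33 BEC and 14 LEC, 47
primary profiles in total, Dataset A a strict subset of Dataset B — plus
4 + 4 cell-line replicates and 3 controls on GPL570 outside both datasets.
The split of the 23 non-GPL570 primary samples between GPL571 and GPL5188
is not printed anywhere and was fixed once at a plausible ratio; totals and
the Dataset A definition are what downstream analyses consume. 100 markers
per class at a 2-log2-unit effect with noise SD 0.5 are the default planted
conditions.

What the generator does **not** emulate: probe-level effects (it draws gene
summaries directly), correlated gene modules, non-random (MNAR)
missingness, within-class donor heterogeneity beyond i.i.d. noise, and
array spatial artifacts. Tests passing on this model therefore validate
the *pipeline arithmetic* — filtering, scaling, testing, FDR calibration,
set arithmetic, embedding geometry — not the biological claim that pooled
real data yields the printed marker lists; those lists enter the package
as transcribed fixtures instead.

## Numerical and edge-case choices

* **SD estimator**: sample ($n-1$) denominator, so the gene $(1,2,3)$
  standardizes to $(-1,0,1)$. Median of an even count is the midpoint of
  the two central values.
* **Degenerate genes**: constant genes (zero SD) and genes with fewer than
  two observed values are dropped at standardization and logged in the
  provenance record, never silently.
* **Degenerate tests**: a group with fewer than two observations, or two
  exactly constant groups with unequal means, make a gene *untestable*
  (`p = NA`); untestable genes are excluded from the FDR input and flagged
  in the output. Two constant equal groups give $t = 0,\ p = 1$.
* **Ties in p** share a q-value by the step-up minimization; output rows
  are kept in gene order for determinism.
* **Missing-value token** in expression TSVs is exactly `NA`; an empty
  cell is a format error — explicitness beats guessing.
* **Gene symbols** are canonicalized by upper-casing and whitespace
  removal, and compound printed labels ("LAMC1, LAMB2") are split on
  commas, since they denote multiple genes sharing a probe. Matching is
  exact after canonicalization; no alias databases.
* **Venn regions** are keyed by sorted study-id tuples and enumerated for
  *all* non-empty subsets, so printed zero-size intersections are
  represented, and region identity is independent of input order.
* **Classical MDS** (double-centering + eigendecomposition) was chosen
  over stress-minimizing variants because it is deterministic — no seeds,
  no convergence tolerances — and exact for Euclidean input. Dimensions
  with negative eigenvalues (non-Euclidean directions, possible under the
  `pairwise_complete` distance policy) are zeroed and the eigenvalue
  reported. The default distance policy `complete_genes` uses only fully
  observed genes and is exactly Euclidean; `pairwise_complete` rescales
  each pair by $\sqrt{n_{\mathrm{total}}/n_{\mathrm{observed}}}$ and is
  only approximately so.
* **Cluster separation** uses the maximum distance of a class member from
  its centroid as the class radius; single-member classes get an `NA`
  radius rather than a fabricated one.

## Interfaces

The exported functions are the interface: per-stage functions
(`mergePlatforms`, `filterMissingness`, `standardizeGenes`,
`differentialTable`, `vennPartition`, `classicalMds`, …) compose freely,
and `runPipeline()` orchestrates simulate → harmonize → differential
calling per dataset → marker intersection → MDS with one seed, writing
TSV/JSON artifacts and a hash-bearing manifest when an output directory is
given. Rerunning any downstream function on unchanged upstream output is
deterministic.

## Validation problem sizes

The shipped test-suite exercises the full default design (19 081 genes,
58 samples) for recovery and embedding checks, 200 replicate null datasets
of 2 000 genes for FDR calibration, and small hand-constructed matrices
for every exact numerical contract. These sizes were chosen to make the
Monte-Carlo assertions statistically sharp (3-standard-error bands) while
keeping a complete run fast enough for routine development.

## Known limitations

* The packaged cross-study gene lists carry only the genes printed in the
  source tables; two single-study columns are truncated there after the
  top 20 genes, so totals for those studies are not reconstructable from
  the fixtures — per-study totals are asserted only where the full list is
  printed (the pooled dataset columns).
* Inputs are assumed to be per-platform normalized log2 summaries;
  probe-level normalization (GC-RMA) and probe reannotation are upstream
  of this package and are not reimplemented.
* `pairwise_complete` distances can break Euclidean geometry; the MDS
  reports, but cannot repair, the resulting negative eigenvalues.
* The robust-FDR $\hat\pi_0$ is accurate when p-values are uniform under
  the null; strong dependence between genes (co-regulation) widens its
  sampling variability, as for all marginal FDR estimators.
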