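---
title: "Methods: longitudinal paired single-cell analysis of leukemia progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal paired single-cell analysis of leukemia progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tpllprog)
```

# Scope and study design

`tpllprog` analyzes paired peripheral-blood single-cell transcriptomes of
T-prolymphocytic leukemia (T-PLL), where each patient contributes one sample
at the indolent (stable, early) disease stage and one after transition to
active disease. The analysis unit is the longitudinal pair; the questions the
package answers are:

1. Which tumor subclusters of a pair gain or lose relative abundance between
   the time points (clonal dynamics)?
2. Which genes change expression between time points, per pair and
   recurrently across patients?
3. Do curated transcriptional programs (gene sets) shift between conditions,
   at the cell, cluster, and sample level?
4. Which somatic short variants survive a tumor-only retention filter, and
   how do their allele frequencies move between time points?

Every statistical stage is exercised end to end on a synthetic cohort with
planted ground truth, so correctness claims are testable without any
sequencing data.

# Preprocessing

Cells are kept when they show between 250 and 4500 detected features
(inclusive) and a mitochondrial count fraction strictly below 20%; a cell
with zero counts has its mitochondrial fraction defined as 0 and fails the
feature floor. Counts are normalized per cell to a scale factor of 10^4 and
transformed with the natural `log1p`, preserving sparsity. The PCA embedding
standardizes the 2000 most variable genes (variance of normalized values) to
zero mean and unit variance, clips standardized values at ±10, and takes the
top 15 components of an exact eigendecomposition; component signs are fixed
by making each loading's largest-magnitude entry positive so the embedding
is bit-reproducible. The HVG count and the ±10 clip are the conventional
defaults of the field's toolkits; both are configurable.

Clustering builds a k = 20 nearest-neighbor graph (Euclidean, self
included), weights edges by the Jaccard overlap of neighbor sets, prunes
weights below 1/15, and optimizes modularity (Louvain) at a caller-chosen
resolution — 1.5 for atlas-level partitions, 5 for the within-pair tumor
subcluster analysis. Labels are 0-based and ordered by decreasing cluster
size. Two properties deserve honesty: modularity optimization at high
resolution deliberately over-partitions homogeneous groups (two pure,
well-separated Gaussian blobs split into ~4 communities at resolution 1.5 —
the same behavior the standard single-cell toolkits show), and Louvain is
order-sensitive where the optimum is degenerate. The tests therefore assert
exact recovery of planted partitions at low resolution and partition purity
(no cluster spans two planted groups) at high resolution.

# Clonal dynamics: differential abundance of subclusters

For a pair with `N_I` indolent and `N_A` active cells over K clusters, the
per-cluster effect size is the log2 fold-difference in proportion

    log2FD(c) = log2( p_A(c) / p_I(c) ),   p_T(c) = (n_T(c) + 0.5) / (N_T + 0.5 K)

with a Haldane-style +0.5 continuity correction so empty cells stay finite
(reference implementations clamp instead; the correction changes nothing at
the cluster sizes where decisions are made). Significance comes from a
two-sided permutation test: the null permutes time-point labels across all
cells of the pair, fixing cluster sizes and the overall indolent/active
totals. Under that null the per-cluster indolent counts are exactly
multivariate hypergeometric, so draws are sampled from that law directly
(sequential `rhyper`), which is distribution-identical to label shuffling
and much faster at B = 10,000. The p-value uses the add-one estimator
`(1 + #{|log2FD_b| >= |obs|}) / (B + 1)`; exceedance is compared with a
1e-9 tolerance so that arithmetically identical count configurations are
tied regardless of floating-point evaluation order. FDR is Benjamini-
Hochberg within the pair, and clusters are classified expanding (FDR < 0.05
and log2FD >= 1), shrinking (FDR < 0.05 and log2FD <= -1), or stable.

The tests verify the sampler against exhaustive enumeration on an 8-cell
instance, type-I calibration on 500 null pairs (acceptance band 3-7% at
alpha = 0.05), and >= 90% sensitivity with <= 10% misclassification for
planted |log2FD| = 2 at >= 150 cells per cluster.

# Differential expression

**Cell level.** Genes expressed in at least `ceil(0.01 * n)` of the pair's
cells are tested with a two-sided Wilcoxon rank-sum test (normal
approximation with tie and continuity correction — the default marker test
of the standard toolkits). Ranking exploits sparsity: all zeros of a gene
share one midrank block and only non-zero entries are sorted, which makes
the per-pair scan linear in non-zero entries; the tests require exact
(1e-10) agreement with a dense textbook implementation, and an optional
exhaustive-enumeration mode covers small groups. The reported fold change
de-logs the group means with a pseudo-count of one:
`log2((mean(expm1 x_A) + 1) / (mean(expm1 x_B) + 1))`. DEGs satisfy
adjusted p < 0.05 (strict) and |log2FC| >= 0.5 (non-strict).

**Recurrence across patients.** The statistic is the number of genes called
DEG in at least k = 2 pairs. The null preserves each pair's DEG count and
tested-gene universe (pairs filter genes independently, so universes
differ): each permutation redraws every pair's DEG set uniformly without
replacement from that pair's own universe. The p-value is one-sided with the
add-one estimator. Direction of deregulation is ignored for overlap
counting, matching how per-pair DEG sets are usually intersected; the
two-pair null is validated against the closed-form hypergeometric law.

**Pseudobulk.** Raw counts are summed per group (sample or cluster). The
methods text of upstream pipelines speaks of aggregating "normalized"
expression, but the downstream count model requires integer counts, so raw
summation is the default (the aggregation function enforces the raw-count
contract). Each gene is fit with a negative-binomial log-linear model with
`offset = log(library size)`; paired designs add patient blocks. The
dispersion is a per-gene method-of-moments estimate shrunk toward the
trimmed-mean common dispersion with weight `n / (n + 10)` — a closed-form
stand-in for empirical-Bayes tagwise shrinkage that is accurate at
pseudobulk scale and easy to test. The condition coefficient is tested by a
likelihood-ratio chi-square with one degree of freedom. Because the offset
is estimated from the counts themselves, a globally unbalanced fold change
is partially absorbed by the library size (the usual compositional
non-identifiability of count models); the calibration tests therefore plant
composition-balanced effects (few up-regulated genes offset by
down-regulated ones), recovering log2FC = 2 with median error below 0.15
and type-I error <= 0.08, and an edgeR LRT cross-check on the same
pseudobulks agrees closely (fold-change correlation > 0.98).

# Gene-set scores

**Module scores** follow the expression-matched control-gene scheme: all
genes are cut into 24 equal-frequency bins of dataset-wide mean expression;
each gene-set gene draws 100 control genes without replacement from its own
bin; the per-cell score is the mean over set genes minus the mean over the
pooled control multiset (duplicates kept, as in the reference
implementation). Ties in the mean-expression ranking are broken by a tiny
seeded jitter so binning is deterministic per seed — the reference tool's
tie handling is undocumented. Scores are computed on the entire dataset
being compared, not per subset. On a constant matrix the score cancels to
exactly zero; for an expression-matched random set it is unbiased.

**Sample-level comparisons** of mean scores use a permutation test built for
cohorts that mix paired and unpaired samples: within-patient pairs are
sign-flipped with probability 1/2, unpaired samples are permuted among
themselves preserving condition counts; two-sided, add-one, B = 10,000. On
a fully paired design this reduces to the exact sign-flip test.

**Activity scores** summarize a gene set per cluster: cluster-mean raw
expression is log1p-normalized, each gene's per-cluster values become
percentile ranks `(midrank - 0.5) / K`, ranks are averaged over member
genes and shifted by -0.5. The `(midrank - 0.5)/K` convention makes
all-tied genes land exactly at 0 and realizes the [-0.5, 0.5] bounds
exactly.

**Metabolic transcript fraction** is the share of a unit's protein-coding
counts that belong to metabolism-annotated genes; per-sample values pool
counts (equivalently, count-weighted means of per-cell fractions), matching
how sample-level transcript proportions are computed in bulk comparisons.
The annotation is user-supplied input; metabolic genes must be a subset of
coding genes (violations are intersected away with a warning).

**Pseudotime orientation.** Trajectory inference itself is out of scope;
the package implements only the orientation rule: min-max rescale to [0, 1]
and flip (`1 - pt`) when indolent cells have a larger mean pseudotime than
active cells, so trajectories always run indolent to active. The flip is an
involution; constant inputs return 0.5 with a warning.

# Somatic short-variant filtering

Variants are read one row per ALT allele (multi-allelic records split),
with depth taken as the sum of allelic depths and VAF = alt reads / depth.
Retention requires VAF >= 0.05, depth >= 10, alt reads >= 3, population
AF <= 0.01, dbSNP MAF <= 0.05 and TOPMed MAF <= 0.05 — all boundaries
inclusive on the pass side. Population-frequency INFO keys are configurable
(annotation dialects differ) and absent annotations are treated as 0, i.e.
they pass those criteria: tumor-only calling leaves many sites unannotated
and filtering on missingness would discard real somatic events. Failing
records carry all violated criteria as reason codes; the filter is monotone
in every threshold and idempotent. VAF trajectories match variants across
time points on the exact (chrom, pos, ref, alt) key — no fuzzy indel
normalization; inputs are assumed left-normalized — and average VAFs per
gene, with variants seen at only one time point contributing 0 at the other
and flagged emergent/lost.

# The synthetic cohort generator

The generator emulates the study design, not any particular dataset: per
patient two samples (indolent, active), cells allocated to K = 6 subclonal
clusters by a multinomial, per-cell library sizes log-normal
(meanlog = log 1500, sdlog 0.35 — a realistic shallow 10x depth over a
5000-gene panel), gene baselines log-normal and shared across patients, and
UMI counts negative-binomial with dispersion 0.4 (no explicit zero
inflation; NB is adequate for UMI data and no stage assumes more). Defaults
follow the reference analysis conditions: 4 patients, 3000 cells per
sample, 5000 genes.

Planted effects are multiplicative on the NB mean so true log2 effects are
exact by construction:

* **Cluster dynamics.** Active-stage proportions move one planted cluster to
  exactly `2^(+2)` times its indolent proportion (0.10 to 0.40) and one to
  `2^(-2)` (0.32 to 0.08); the remaining clusters rescale proportionally
  (0.145 to 0.13, a passive log2FD of -0.16, far inside the stable band).
* **DEGs.** 30 recurrent genes are up-regulated (log2FC = 2) at the active
  time point in every patient and 20 private genes in exactly one patient.
  The strong effect size reflects progression-stage transcriptional shifts
  and keeps the planted truth detectable at the per-pair DEG gates after the
  attenuation inherent in the de-logged fold-change estimate.
* **Subclone program.** A 50-gene signature is multiplied by 4 in the
  planted expanding clusters at both time points. Note a realistic
  consequence: because those clusters grow, program genes also become
  cell-level DEGs between time points through composition alone.
* **QC structure.** 13 genes are flagged mitochondrial and scaled so their
  expected count share is 5%; 80% of genes are protein-coding, 10%
  metabolic (subset of coding).
* **Variants.** Three ATM lesions with VAF rising from ~0.70 to ~0.91 and
  two stable subclonal JAK/STAT variants, binomial reads at depth 500.

What the generator does **not** model: doublets, ambient RNA, batch effects
between patients (integration internals are out of scope — the pipeline
accepts any joint embedding), cell-type heterogeneity beyond tumor
subclusters, and library-size differences between conditions. Passing tests
therefore demonstrate the statistics are correct and calibrated under the
generative assumptions, not that any particular biological dataset will
show these effect sizes.

# Pipeline, seeds, and reproducibility

`run_pipeline()` chains QC, normalization, per-pair cluster labels (from
metadata when present, otherwise joint PCA + SNN at resolution 5),
differential abundance, per-pair Wilcoxon DE, the recurrence test, the
paired pseudobulk NB-LRT, module/activity/metabolic scoring, and the
variant filter with VAF trajectories. One global seed derives per-stage
seeds by hashing stage names (`derive_seed()`), so stages are individually
reproducible; reports are byte-identical under identical config and seed,
and every output embeds the seed and a config checksum. A stage failure
aborts with the stage name and cause.

Problem sizes in the test suite are chosen to make each statistical claim
sharp at desk scale: 500 null pairs for type-I calibration, 100 pairs for
planted-shift recovery, 2000-gene pseudobulk simulations, 100 seeded
replicates for the planted-signature ranking, and the full 24,000-cell
reference cohort for the end-to-end recovery check.

# Known limitations

* The NB dispersion shrinkage is method-of-moments, not empirical Bayes;
  at very small pseudobulk replication (2 vs 2) the LRT can be mildly
  anticonservative, which the calibration bound (type-I <= 0.08) makes
  explicit.
* The permutation differential-abundance test conditions on cluster labels;
  uncertainty in the clustering itself is not propagated.
* Compositional non-identifiability: fold changes are relative to the
  per-sample library size; globally unbalanced shifts are partially
  absorbed by the offset.
* Variant matching is exact-key; indel representation differences must be
  resolved upstream.
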