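---
title: "Methods: models, parameters and design choices"
author: "neurotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neurotrace` implements the downstream computational analysis of traced
peripheral-neuron transcriptomes and their tumour-microenvironment (TME)
interaction partners: quality control, normalization, reference-based
annotation, pseudobulk differential expression (DE), consensus up/down
signature construction, gene-set enrichment, and ligand–receptor
interaction-potential scoring. The pipeline starts at count matrices;
alignment, quantification and any imaging analysis are out of scope. A
seeded synthetic-data generator with recorded ground truth stands in for
deposited data so that every stage is testable offline.

# The synthetic-data generator

The generator defines the study conditions that all tests and the
acceptance script run under. It emulates two designs:

**Plate-based traced neurons** (Smart-seq2-like). Five neuronal
subpopulations — two sympathetic celiac-ganglion clusters (CG1, CG2) and
three sensory DRG subtypes (NEFM, PEP, NPEP) — over 2 healthy and 3
tumour biological replicates, 55 cells per subpopulation per replicate by
default (≈1,375 neurons, the scale of the study this package targets).
Counts are negative-binomial: gene $g$ in cell $c$ has mean
$\mu_{gc} = b_g \cdot 2^{\Delta_{gc}} \cdot d_c/\bar d$ and variance
$\mu + \alpha_g \mu^2$, where

* $b_g$ is a log-normal baseline mean (meanlog $\log 40$, sdlog 1.2 —
  a right-skewed expression distribution typical of deep plate data);
* $\Delta_{gc}$ collects log2 effects: subpopulation markers (default 50
  genes per subpopulation at log2FC 2) and planted condition-specific DE
  sets applied to tumour cells of affected subpopulations;
* $d_c$ is a log-normal per-cell depth (meanlog $\log 5\times10^5$,
  sdlog 0.4, Smart-seq2 scale), recorded as `mapped_reads`;
* $\alpha_g$ follows a declining mean–dispersion trend
  $\alpha(m) = 0.1 + 1/m$ by default, because the DE stage's dispersion
  shrinkage assumes such a trend exists; a constant dispersion is
  available.

The per-cell mitochondrial fraction is Beta(20, 230) (mean 8%, tight
enough that healthy cells essentially never cross the 20% QC cap), and
mitochondrial/nuclear genes are reapportioned per cell so the expected
mitochondrial fraction equals the drawn one. A configured fraction of
cells is planted as low-quality — exactly `round(fraction * n)` cells,
alternating between depth set to 50% of the read threshold and
mitochondrial fraction set to 1.5× the cap, so each QC rule is exercised.

**Droplet-based TME** (10X-like). Six cell types (PDAC, epithelial,
endothelial, immune, CAF, fibroblast) over 3 healthy and 4 tumour
replicates on a two-species universe: the mouse genes plus a 1,000-gene
human block. Cancer cells draw 90% of their UMIs from the human block
(other types 2%), making species assignment testable. Each type carries
fixed per-gene identity effects (sd 0.5 log2) — without true between-type
differences, cross-type z-scores would amplify pure noise. UMI depth is
log-normal (meanlog $\log 8000$, sdlog 0.3) and the droplet mitochondrial
fraction Beta(30, 970) (mean 3%, typical of sorted cells); both leave
comfortable margins to the droplet QC thresholds so that the only cells
failing QC are the planted ones. All six types are present in both
conditions (a small CAF-like state exists in healthy tissue), which keeps
the interactome's min-subtraction frame well-defined.

What the generator does **not** emulate: read-level data, doublets,
ambient RNA, batch effects beyond replicate labels, or replicate-level
biological variability (replicates differ only by sampling). Passing
tests therefore demonstrate correctness of the algorithms under a clean
NB model, not robustness to real-data artefacts. One stochastic caveat:
droplet QC measures the realized mitochondrial fraction from counts, so a
planted high-mito cell (expected fraction 0.15) can, with probability
around $10^{-4}$ per cell, realize below the 0.10 cap; plate QC applies
thresholds to the planted metadata and is exact.

# Quality control and normalization

Boundary semantics are literal: "fewer than X" removes strictly below X
(a cell at exactly 50,000 reads is kept); "more than Y" removes strictly
above Y. Plate cells need ≥50,000 mapped reads, ≥4,000 detected genes
(count > 0) and ≤20% mitochondrial reads (from metadata); droplet cells
need ≥1,000 UMIs, ≥500 detected genes and ≤10% mitochondrial counts
(computed from `mt-`-flagged genes). The three predicates are independent
conjunctions, so filtering is idempotent and order-free. Species labels
require a strict majority (>50%) of counts; exact ties are "ambiguous"
and excluded downstream.

Size factors are median-of-ratios (geometric-mean reference, median of
per-cell ratios) rescaled to geometric mean 1, with library-size factors
as the alternative. Median-of-ratios is a bulk estimator: on sparse
droplet counts its positive-observation fallback is measurably biased
(we observed >2-fold type-dependent inflation for expression-shifted cell
types), so the pipeline uses median-of-ratios for deep plate data and
pseudobulk libraries and library-size factors for droplet data. Log
transformation is `log2(count/factor + 1)` throughout; base and
pseudocount are recorded in the object.

# Annotation

Highly variable genes are those with the largest positive residual of
log-expression variance over a second-degree polynomial mean–variance
trend (ordinary least squares); ties break lexicographically by gene id.
The default of 1,000 HVGs mirrors common practice for integration-scale
feature sets. Label transfer correlates each query cell with each
reference-type centroid (Pearson) over the HVG intersection and assigns
the best-correlated type; margins, runner-ups, exact ties (flagged,
lexicographic tie-break) and undefined correlations ("unassignable") are
reported. A Spearman-based annotator provides an independent second
opinion for the concordance check — rank correlation is invariant to
monotone transforms, so agreement between the two is informative.

Clustering builds a k-nearest-neighbour graph (Euclidean, on 50 PCs by
default), weights edges by shared-neighbour counts
$|shared|/(2k - |shared|)$, and partitions with Louvain. Louvain is
node-order dependent; the order is shuffled once from the seed, so
results are reproducible. Labels are 0..C−1 by decreasing size. The
number of neighbours `k` should be small relative to the expected
cluster size but large enough for within-cluster cohesion; the package
default is 10.

# Differential expression

Cells are summed into pseudobulk libraries per replicate × condition
(optionally × subpopulation) so inference operates on biological
replicates. The Wald test per gene:

1. median-of-ratios size factors across libraries;
2. method-of-moments dispersion from the pooled within-condition variance
   of normalized counts, $\hat\alpha = (s^2 - \bar{s^{-1}}\mu)/\mu^2$;
3. a mean–dispersion trend $\alpha(\mu) = a_0/\mu + a_1$ fitted by least
   squares on the *unfloored* moment estimates — the estimates are
   unbiased but heavily right-skewed at few replicates, so a
   median-targeting robust fit would systematically underestimate the
   trend, and dropping negative estimates would bias it;
4. the working dispersion is a weighted average
   $w\,\alpha_{trend} + (1-w)\,\hat\alpha$;
5. a log-link NB GLM with a condition indicator, fitted by iteratively
   reweighted least squares (the two-level design decouples into two
   one-parameter fits with offsets), Wald $z$ from expected information,
   two-sided p from the standard normal, Benjamini–Hochberg adjustment
   over genes with nonzero counts.

**Why the trend weight defaults to 0.75.** With 2 vs 3 libraries the
gene-wise variance carries ~3 degrees of freedom, so
$\hat\alpha \approx \alpha\,\chi^2_3/3$. Even with an exact trend, a
weight of 0.5 yields a type-I error of
$E[2\Phi(-1.96\sqrt{0.5 + 0.5\chi^2_3/3})] \approx 0.068$ at the nominal
0.05 — irreducibly anti-conservative. At $w = 0.75$ the same expression
gives ≈0.056, and the measured null fraction of p < 0.05 on synthetic
pseudobulk (2,000 genes, no effects) is 0.047–0.062 across seeds. The
weight is configurable; `dispersions` can also be supplied directly,
which is how the test suite verifies the Poisson limit (agreement with a
Poisson GLM within $10^{-3}$ on $z$ as $\alpha \to 0$).

Where a condition lacks replicates the per-cell Wilcoxon rank-sum test is
the fallback: exact enumeration when both groups have ≤10 cells (and no
ties), normal approximation with tie and continuity correction otherwise;
fully tied genes report p = 1. The default significance rule everywhere
is BH-adjusted p < 0.1.

# Consensus signature

Per subpopulation, genes are ranked by the Wald statistic (descending for
the up list, ascending for the down list), truncated to the top 500, and
then filtered: mean normalized expression in that population (conditions
pooled) below 500, or adjusted p above 0.2, excludes a gene
(truncate-then-filter, strict boundaries). Consensus membership requires
≥3 contributing subpopulations for down-genes and ≥2 for up-genes; genes
whose contributors are all CG-type are removed, because effects seen only
in the sympathetic ganglion do not generalize to a pan-neuronal
signature. A gene qualifying in both directions is dropped from both sets
and logged — disjoint sets keep enrichment well-defined. The ranking
metric, expression scale for the mean filter, and all thresholds are
parameters; the statistic was chosen as the ranking because it blends
effect size and precision.

# Enrichment

The weighted Kolmogorov–Smirnov running sum: hits advance by
$|s|^p/\sum_{hits}|s|^p$ (default $p = 1$), misses retreat by
$1/(N - |set|)$, and the enrichment score is the signed maximum
deviation. When the positive and negative extremes tie in magnitude the
positive one is returned (the convention of reference GSEA
implementations; ties are compared with a $10^{-12}$ epsilon so float
summation order cannot flip the sign of an exactly balanced excursion).
The null is **gene-set permutation** — random same-size sets — rather
than phenotype permutation, which is degenerate at 2–3 replicates.
NES divides the observed score by the mean magnitude of sign-matching
null scores; $p = (1 + \#\{\text{as extreme, same sign}\}) /
(1 + \#\{\text{same sign}\})$, BH-corrected across sets. All permutation
draws are seeded.

# Interactome

A ligand or receptor counts as expressed in a neuron group when
$\log_{10}(\text{aggregate counts} + 1) > 2$ (≈100 reads over the group;
natural log available by flag). For each sender group, the cognate genes
(partners of expressed ligands/receptors) are scored in the TME: per
replicate, mean log expression per receiver type, z-scored per gene
across receiver types using the population (n-denominator) standard
deviation, zero-variance genes contributing 0; the potential is the mean
z over cognate genes minus the minimum over the whole comparison frame
(all receiver types and replicates of both conditions), so healthy and
tumour potentials share a scale and the frame minimum is exactly 0.
Potentials are frame-relative by construction: removing a receiver type
changes all values, which the test suite asserts rather than assumes
away.

Pair-level ranking multiplies the neuron-side mean log expression of the
expressed gene (per sender group and condition) by the z-scored
receiver-type mean of its cognate (z within condition, replicates
pooled); both orientations are scored when the sender expresses both
sides, pairs with neither side expressed are excluded; the delta is
tumour − healthy, ranked by magnitude, top 10 per sender by default.

# Problem sizes and runtime choices

Tests and the acceptance analysis run at 1,000–1,375 cells × 2,000–5,000
genes for plate data and ~1,260 cells × 3,000 genes for the TME, with
1,000 enrichment permutations and a 1,000-replicate null-uniformity
check — sizes at which every property of interest (QC exactness,
annotation recovery ≥95%, DE calibration within its binomial band, power
≥0.9 at |log2FC| = 2, signature recovery ≥90%, interactome recovery) is
decisively measurable while a full run stays in the order of minutes on
one CPU. Scenario plantings use robustly expressed genes (baseline ≥1,500
for signature scenarios) so the publication-scale mean-expression filter (≥500)
operates as intended rather than silently emptying the candidate lists.
Demo-scale pipeline runs (1,200 genes, 20 cells per subpopulation per
replicate) scale the detected-genes QC threshold to the gene universe.

# Known limitations

* Calibration of the Wald test is demonstrated under the generator's NB
  model without replicate-level random effects; real pseudobulk data with
  extra between-replicate variability will be served better by a higher
  trend weight or more replicates.
* Median-of-ratios size factors should not be applied to sparse droplet
  matrices (see above); the pipeline guards this by modality, not by
  sparsity detection.
* The annotators are nearest-centroid methods; they do not model per-cell
  reference heterogeneity and will be overconfident for query types
  absent from the atlas.
* Gene-set permutation tests set enrichment against a random-gene null,
  not against expression-correlation structure; correlated gene blocks
  can inflate significance on real data.
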