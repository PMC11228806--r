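---
title: "Methods: segment-level analysis of tumor and TME ecosystems"
author: "tmeco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment-level analysis of tumor and TME ecosystems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmeco)
```

## The problem

NanoString GeoMx digital spatial profiling (DSP) yields one whole
transcriptome per user-drawn tissue segment. In a paired tumor /
tumor-microenvironment (TME) design — such as metastatic small-cell lung
cancer (SCLC) profiled by rapid autopsy — each region of interest is split by
pan-cytokeratin staining into a tumor segment and a TME segment, plus a few
tumor-only and histologically normal segments. The scientific questions this
package addresses are: which tumor phenotypes (neuroendocrine, hybrid-NE,
non-NE) are present and where; how the cellular composition of the adjacent
TME tracks the tumor phenotype; which ligand-receptor channels connect the
two compartments; and whether TME-derived signature scores (for example a
matrix-remodeling cancer-associated-fibroblast state) stratify survival.

Every stage is driven and verified by a synthetic-data generator that plants
known ground truth, so the full pipeline is testable without any external
download.

## Probe-level processing

**Probe collapse.** Each gene is probed several times; the gene value is the
arithmetic mean of its probe counts after outlier removal. The outlier rule
is: with at least three probes, drop probes outside 0.1x-10x the per-segment
median of the gene's probes. The rule is deliberately robust at the 3-probe
counts typical of whole-transcriptome panels, where formal outlier tests
have no power; with one or two probes no probe is dropped. If the rule would
drop every probe of a gene in a segment, all are kept (the median is then
the only defensible location estimate).

**Limit of quantification.** Per segment, LOQ = geometric mean of the
negative-control probe counts plus `n_sd` (default 2) standard deviations.
Zeros are replaced by a pseudo-count of 1 before the geometric mean, and the
standard deviation is by default the arithmetic sample sd of those counts —
the literal reading of "geometric mean plus two standard deviations". A
multiplicative alternative (geomean x geometric-sd^n) is available via
`sd_type = "geometric"` because the phrase is genuinely ambiguous; the
additive form is the default and both are tested.

**Segment QC.** Segments fail on sequencing saturation (default threshold
0.80), nuclei count (default 20) or the fraction of genes above their LOQ
(default 5%). Thresholds of zero disable a check. The default synthetic
cohort plants two low-saturation TME segments, reproducing the common
32 -> 30 TME attrition pattern.

**Q3 normalization.** Each segment's third quartile — computed over its
above-LOQ genes only, the standard DSP convention — is scaled to the
geometric mean of all segments' Q3 values, followed by log2(x + 1). States
are tracked explicitly (`raw` -> `q3` -> `log2q3`) and transitions are
one-way: re-normalizing raises an error instead of silently
double-normalizing.

## Phenotype discovery

Clustering operates on the top-n highly variable genes (variance across
segments, alphabetical tie-break; n = 500 in the synthetic conditions,
configurable) of the log2-Q3 tumor matrix, with Euclidean k-means
(50 iterations, 200 restarts, best of restarts by WSS; k-means++-style
seeding via `stats::kmeans`'s `nstart`). The number of clusters is the elbow
of the total within-cluster sum of squares over k = 1..10, automated as the
argmax of the second forward difference — the discrete curvature — over
k = 2..9. If all WSS are numerically zero the data are degenerate and k = 1
by convention. Cluster labels are renumbered by ascending cluster mean of an
orienting score (the NE score by default), so cluster 1 is always the least
and cluster k the most NE-like regardless of k-means label permutation.

**PC-contribution signatures.** On the HVG PCA (segments as observations,
centered, unscaled), the contribution of a gene to a component is its
squared loading normalized by the column sum. A gene is a *contributor*
when its contribution exceeds the uniform expectation 1/|universe|; each
contributor is assigned to the single axis (PC1 or PC2) where it contributes
more, which guarantees the three signatures are pairwise disjoint.
Signature 1 = PC1-assigned contributors with positive PC1 loading,
signature 2 = PC2-assigned with positive PC2 loading, signature 3 =
PC2-assigned with negative loading. Because the sign of a principal axis is
arbitrary, each component is first oriented so its largest-|loading| gene is
positive; this pins the convention deterministically but cannot dictate
*which* planted program lands on which axis/sign cell — that is decided by
the cluster geometry. Recovery tests therefore match signatures to planted
programs by maximal overlap, and the orientation rule itself is tested by
its exact sign-flip symmetry (flipping PC2 swaps signatures 2 and 3).

**Markers.** One-vs-rest two-sided Wilcoxon rank-sum per gene with fold
change log2(median Q3 in cluster / median Q3 in rest) on un-logged values;
a marker requires p < 0.05 and linear fold change > 2. Zero medians receive
a pseudo-count of 1 and are flagged. TME segments inherit the cluster of the
tumor segment sharing their region; unpaired TME segments are flagged
unassigned rather than guessed.

## Scoring

**ssGSEA.** Genes are ranked per sample (descending, alphabetical
tie-break for cross-platform determinism). With rank values N..1 and
weights rank^alpha (alpha = 0.25), the enrichment score is the sum over all
positions of the weighted in-set cumulative frequency minus the uniform
out-of-set cumulative frequency. The score is invariant to any strictly
monotone transformation of a sample's values. Optional normalization
divides the whole matrix by its global max - min. A caveat the synthetic
tests quantify: ssGSEA is rank-compositional, so strongly regulated
programs displace the ranks of background genes, and "decoy" sets are not
an exact between-group null — their group differences are real but small
(3-17% of a planted program's difference in the default conditions).

**NE score.** (rho_NE - rho_nonNE) / 2, the difference of Pearson
correlations between a segment's signature-gene profile and NE / non-NE
reference profiles, bounded in [-1, 1] and antisymmetric under swapping the
profiles. Reference profiles are data inputs (the generator supplies
synthetic ones), not hard-coded gene lists.

**Purity.** Ordinary least squares purity ~ stromal + immune on training
triples where purity is known; predictions are clamped to [0, 1] with a
flag, and collinear predictors (condition number > 1e8) are rejected.

**Shannon diversity.** H' = -sum p_i ln p_i with 0 ln 0 = 0; vectors whose
sum deviates from 1 by more than 1e-6 are renormalized with a warning.

**H-score.** 1x(% weak) + 2x(% moderate) + 3x(% strong) stained nuclei,
range 0-300.

**Preranked GSEA.** Weighted Kolmogorov-Smirnov enrichment (weight =
|metric|, exponent 1) with a gene-label permutation null; p-values compare
same-sign null scores, NES divides by the mean |null ES| of matching sign,
and BH correction runs across sets. The ranking metric from a marker table
is -log10(p) signed by the fold-change direction, with p = 0 floored at the
smallest representable double.

## Deconvolution

Per TME segment, linear-scale (q3) expression is modeled as a non-negative
mixture of reference cell-type profiles: Lawson-Hanson active-set NNLS
followed by renormalization onto the simplex. Mixtures are additive in
linear space, which is why deconvolution never runs on log values, and the
simplex renormalization absorbs library-size scale, making the result
invariant to positive per-segment rescaling. An alternative `"augmented"`
mode enforces sum-to-one through a stiff penalty row after an NNLS
pre-scaling step. The residual is the relative fitted-norm error. The
ν-SVR machinery of web-based deconvolution tools is intentionally out of
scope; the linear mixture model is the recoverable, testable core, and
noiseless mixtures are recovered to solver tolerance (1e-6) while
negative-binomial noise at the default cohort size keeps the mean absolute
proportion error under 0.05.

## Tumor-TME communication

Expression is min-max rescaled per gene to [0, 10] across all segments in
the run, so pair scores are bounded and comparable across pairs. Ligand
(receptor) activity is the geometric mean of the subunit expressions in the
sender (receiver) segment of a paired region; the pair score is
sqrt(ligand x receptor). A missing subunit gives a missing score — absence
of measurement is not absence of signal. Population-level summaries take
the maximum pair score per (sender population, receiver population); the
mean-of-min aggregator (minimum of the two activities per pair, averaged)
is the cross-check and is always dominated by the max. Differential
interactions between ecosystem groups use an exact two-sided Wilcoxon
rank-sum across regions (the exact null matters: at 6 vs 6 regions the
normal approximation cannot clear BH at FDR 5% even for complete
separation) with BH correction and the difference of group medians as the
effect.

## Survival stratification

Cohorts are dichotomized at an empirical score quantile (default 0.75,
type-7 linear-interpolation convention, ties at the cutoff to the low
group). Kaplan-Meier curves, the two-group log-rank test, and a Cox
proportional-hazards fit (Efron ties; univariable headline, optional
declared covariates) report the high-vs-low hazard ratio with Wald 95% CI.
A cohort without events has no defined log-rank test and errors; a group
without events flags the test unstable.

## The synthetic cohort generator

The default `synthetic_config()` emulates the study conditions: 10
patients x 4 regions = 40 ROIs, of which 4 tumor-only, 4 normal and 32
paired (36 tumor, 32 TME, 4 normal segments); ~1000 genes x 3 probes plus
32 negative probes; negative-binomial counts (dispersion 10, chosen as
typical overdispersion for DSP counts) around phenotype-specific means;
sequencing saturation 0.85-0.99 except two planted low-saturation TME
segments; 8 TME cell types with 20 markers each.

Three phenotype programs of 60 genes are planted. The NE program is
elevated 6x in NE segments; the non-NE program 9x (1.5 x fold) in non-NE
segments; hybrid segments express their own EMT metaprogram at 6x plus the
NE program at a mild intermediate 1.15x. These constants were chosen by a
design sweep so that the three centroids satisfy, simultaneously and at
every seed: (i) near-equidistance, so the WSS elbow lands at k = 3;
(ii) the non-NE centroid dominating PC1; (iii) the NE-vs-hybrid contrast
falling on PC2 — the geometry in which positive/negative PC contributors
recover the planted programs. A literal "hybrid = 50% of each other
centroid" design makes the centroids collinear and is unrecoverable by any
two-axis contribution rule, which is why the hybrid instead carries its own
metaprogram, consistent with hybrid states described by EMT metaprograms
co-occurring with intermediate NE marker expression.

Phenotypes are apportioned to tumor regions by largest remainder of the
configured fractions and shuffled — a real cohort has one fixed composition,
and multinomial sampling occasionally produces degenerate 6-segment groups
that no method could recover. TME composition is drawn from a Dirichlet
whose mean interpolates, with weight `mixing_link_strength`, between a
neutral composition and a phenotype-linked target (CAF-dominated for
hybrid, macrophage/CAF-rich for NE, immune-rich for non-NE); at strength 0
composition is exactly independent of phenotype. Tumor segments mix the
phenotype profile with a generic TME profile at planted purity 0.92-0.99.
Active ligand-receptor pairs couple immune-cell ligands to non-NE tumor
receptors so the non-NE ecosystem carries more interactions. Survival
cohorts draw exponential event times with the hazard multiplied by the true
HR above the score cutoff and independent exponential censoring calibrated
to a target censored fraction (default 20%, median low-arm survival 12
months).

What the generator does *not* emulate: spatial coordinates and
image-derived features, patient-level correlation of phenotypes, batch and
slide effects, probe sequence biology, and zero inflation beyond the
negative binomial. Passing tests therefore demonstrate correctness of the
algorithms under the planted statistical structure, not performance on any
real cohort.

## Numerical conventions and degenerate inputs

Quantiles are type-7 throughout. Ranking ties break alphabetically by gene
name. Seeds are taken modulo 2^31 before use. k-means on data with fewer
distinct points than centers returns one cluster per distinct point with
zero WSS. Geometric means replace zeros by 1. All multiple-testing
correction is Benjamini-Hochberg, reported at FDR 5%. Problem sizes in the
test-suite recovery studies — 50 cohorts for clustering, 500 cohorts for
hazard-ratio recovery, 1000 for log-rank calibration, 60 segments for
deconvolution — were chosen so each planted effect is measured with
comfortable Monte-Carlo margin at desk scale.

## Limitations

The deconvolution solver is a simplex-constrained least-squares stand-in
for ν-SVR-based tools; on well-conditioned references they agree in the
mixture-model regime, but the SVR variant's feature selection is not
reproduced. The ligand-receptor score follows the bounded geometric-mean
convention; other tools' exact rescaling defaults differ. The elbow rule is
one reproducible automation of a visual heuristic; other k-selection
criteria (gap statistic, silhouette) may disagree near balanced geometries.
The PC-contribution signature rule presumes the first two components
capture the phenotype plane, which holds for three well-separated clusters
but not for more complex structure.
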