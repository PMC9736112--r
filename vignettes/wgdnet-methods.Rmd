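---
title: "Methods: GG coexpression networks in WGD-stratified tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GG coexpression networks in WGD-stratified tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes, why each
statistical choice was made, and what the synthetic-data tests do and do not
demonstrate.

## The analysis in one paragraph

Tumour cohorts are split into WGD+ and WGD− samples from copy-number-derived
ploidy calls (ABSOLUTE-style tables), keeping only samples with purity
strictly above 0.5. Genes differentially expressed between the two arms
(pAdj < 0.05 and |log2FC| > 0.5, both strict) are tested for enrichment of a
combined gametogenesis-related (GG) catalogue — cancer–testis, germ-cell, and
meiosis genes plus a curated addendum — using exact binomial tails. Cohorts
with at least 50 WGD+ samples after the purity cutoff and at least 100
upregulated genes proceed to coexpression analysis: the WGD+ expression
matrix is filtered for low expression (at least 2 TPM in at least 20% of
samples, a count of `ceiling(0.2 * n)`), a hard |r| threshold is calibrated
against surrogate data, and the unsigned binary-adjacency network over the
upregulated genes is summarised by its giant component, clustering
coefficient, shortest paths, MCL modules, and annotation-module enrichment.
The proteome variant first stratifies samples by hierarchical clustering
with a fixed tree cut, filters lowly expressed proteoforms (at least 5 units
in at least 20% of samples), and imputes missing abundances at the observed
minimum before correlating GG proteoforms.

## Statistical components

### Enrichment among ploidy-regulated genes

The background proportion `p0` is the GG share of the *tested universe* —
the genes present in the DE table — not of the whole genome. "Compared to
the whole transcriptome" is read as the transcriptome actually assayed;
using the genome would overstate enrichment whenever the assay panel is
GG-poor. Enrichment among upregulated genes is the exact right tail
`P(X >= k)` of `Binomial(n_up, p0)`; depletion among downregulated genes is
the exact left tail. Both are computed by `pbinom`, i.e. exact summation
with no normal approximation.

The *trend* test asks whether differentially expressed GG genes skew
towards upregulation beyond the cohort's overall skew: the GG-up count among
all GG-DE genes is tested against `q0 = n_up / (n_up + n_down)`. The
construction of this test was genuinely open; testing against the cohort's
own up-fraction controls for cohorts where nearly everything moves one way.

Duplicate gene symbols in a DE table keep the row with the smallest
adjusted p; the number of dropped rows is reported. Thresholds are strict
inequalities on both axes, so a gene at exactly pAdj = 0.05 or
|logFC| = 0.5 is excluded.

### Threshold calibration by surrogate data

The hard threshold that turns a correlation matrix into a network is not
chosen by eye: for each candidate in (0.6, 0.7, 0.8, 0.9), the number of
links (unordered pairs with |r| at or above the candidate — the bound is
inclusive) in 50 randomly picked 300-gene sets is compared with the same
statistic after independently permuting each gene's values across samples,
50 shuffles per set. The permutation destroys all inter-gene correlation
while preserving each gene's marginal distribution exactly, so the
surrogate counts estimate the noise floor of the cohort. A one-sided
unpaired Wilcoxon rank-sum test (real greater than surrogate, normal
approximation with tie correction; a fully tied comparison yields p = 1)
is run per candidate, and the smallest candidate with p < 0.001 is chosen —
the network should be as inclusive as the noise floor allows. If no
candidate passes, no network is built and the pipeline stops with the
reason logged.

Two readings of "shuffling across columns" were possible; permuting each
gene's sample values independently is the standard correlation-null
surrogate and is what the implementation does. Whether the rank-sum test
should pair set with shuffle was also unstated; the pooled unpaired form is
used because the per-set real count and its 50 surrogate counts are not
meaningfully paired quantities. Calibration gene sets are drawn without
replacement within a set and independently across sets. When the matrix has
fewer rows than the set size, the set size is lowered to the row count with
a warning — note that all "random" sets are then identical and the rank-sum
replicates are no longer independent, so calibration on pools barely above
the set size should be interpreted cautiously.

The inner loop (row permutation, correlation via BLAS, link counting) is
implemented in C++ (RcppArmadillo) and draws from R's RNG, so a single
`set.seed`/`seed =` governs the whole procedure and results are
bit-reproducible.

### Networks and their statistics

Edges are unsigned: positive and negative correlations both count, and the
signed r is kept as an edge attribute. Isolated nodes are retained.
Correlations of constant genes are defined as 0 and flagged rather than
propagating NaN.

The average clustering coefficient follows the Cytoscape NetworkAnalyzer
convention — nodes of degree < 2 contribute 0 to the mean — because that is
the convention under which the published statistics of such networks are
typically computed; excluding those nodes is available behind
`drop_low_degree = TRUE`. The average shortest path length is defined on a
connected graph only and the pipeline computes it on the giant component.
A giant-component size tie is broken towards the lexicographically smallest
node set, with a warning, so results are deterministic.

### MCL

No R implementation of the Markov Cluster algorithm was available in the
supported dependency set, so the package implements it directly as dense
matrix iteration: column-normalise the binary adjacency with unit
self-loops, then alternate expansion (matrix power, default 2) and
inflation (entrywise power with the "granularity" exponent, default 2.5,
followed by renormalisation), pruning entries below 1e-5, until the maximum
entrywise change falls below 1e-6 or 100 iterations. Clusters are read from
the attractor structure of the limit matrix: rows with a positive diagonal
span their supported columns; attractor rows with overlapping support are
merged (one attractor system); residual overlaps go to the larger cluster
with a warning; unattracted nodes become singletons. Cluster ids are
assigned by decreasing size with ties broken by smallest member index, so
the output is deterministic and invariant to node relabelling. Edge weights
are ignored by default (binary adjacency) with a weighted mode behind a
flag, since the upstream network is itself binary.

### Over-representation and multiple testing

Annotation terms (GMT) are intersected with an explicit background universe
before testing; the universe is never defaulted to the genome. The test is
the exact right tail of the hypergeometric distribution, and family-wise
error is controlled by Holm's step-down procedure (`p.adjust`), which never
rejects less than Bonferroni. Terms smaller than 3 after intersection are
reported but flagged low-power.

### Phylostratigraphy

Gene ages are data, not computation: the annotation file maps symbols to
strata 1–16 (1 oldest). Profiles count set members per stratum; genes
missing from the annotation are counted and reported, never silently
dropped, and excluded from proportions. Enrichment against a reference
profile uses the same hypergeometric right tail per stratum. A "peak" is a
stratum whose proportion strictly exceeds both neighbours (ends compare to
their single neighbour) — a deliberately simple operationalisation of what
is usually judged visually. Cohorts qualify for a GG profile when they have
strictly more than 10 upregulated GG genes.

### Proteome preparation

Sample stratification clusters the samples on Euclidean distances with
complete linkage (the `hclust` default) after replacing missing values with
0 for the distance computation only, so abundance and the pattern of
missingness both shape the tree — the missingness pattern is usually the
stronger batch signal. The tree is cut at a fixed height; the paper-scale
default is 1400, and `cut_height_for_k()` returns the height that yields a
desired cluster count for data on other scales. Minimum imputation replaces
every missing cell with the global observed minimum of the matrix — the
"lowest measurable value" reading — under the missing-not-at-random
assumption that low abundance caused the missingness. A per-feature minimum
was the alternative reading; the global minimum was chosen because
per-feature minima collapse to the feature's own noise floor for
heavily-missing features. Note the interaction documented by the tests:
features whose abundance straddles the detection boundary come out of
imputation with their correlations diluted, which bounds how much of a
planted module survives into the network.

## The synthetic-data generators

The generators emulate the statistical structure each stage assumes, with
ground truth for recovery tests.

*Transcriptome defaults*: 2000 genes by 500 samples, 220 WGD+ (a large
breast-carcinoma-scale cohort), purity uniform on (0.3, 1), GG membership
Bernoulli at 7.5% (the approximate share of a 1474-gene catalogue in an
assayed transcriptome), GG upregulation at 0.21 in WGD+ against a 0.07
background (threefold), GG depletion among downregulated genes (0.01
against 0.07), and log2 effects of mean 1. GG assignment is Bernoulli
rather than a fixed count so that the null configuration of the enrichment
test matches the binomial sampling the test assumes. Planted coexpression
modules use one latent factor per module,
`x = sqrt(rho) f + sqrt(1 - rho) e`, giving pairwise correlation rho in
expectation (default six modules of 15 genes at rho 0.75, four of them
carved from GG genes as "meiotic" modules). Module factors share a global
factor so genes of different modules correlate at `rho_between` (default
0.5): without it the module networks fall apart into disconnected cliques,
where real coexpression networks show one giant component containing about
half the upregulated genes. The DE table is analytic — planted genes are
guaranteed past the strict thresholds and unplanted genes are guaranteed
inside them — so filter tests have exact truth instead of refitted
estimates. Phylostratum labels are drawn from a GG distribution peaking at
strata 2 and 8 with secondary mass at 12 and 14, against a broad
old-gene-heavy background.

*Proteome defaults*: 12000 proteins by 505 samples in six planted blocks
(the largest of 142), log2 normalised abundances, 30% marginal missingness.
Missingness is MNAR: a logistic function of true abundance with scale 1.2
log2 units, calibrated by root-finding so the marginal rate is met exactly
in expectation. The steep scale makes each block's observed-protein set
nearly deterministic, and each block additionally carries a high-missingness
signature on a random 8% of proteins — the batch-like patterns that real
cohort trees split on. GG proteins (12%) are mostly low-abundance (germline
genes are largely silent in somatic tissue) except the planted modules
(fourteen modules of 35 at rho 0.7), which are robustly expressed; about 5%
of genes contribute two proteoforms (`SYMBOL.1`, `SYMBOL.2`), which remain
distinct network nodes and map back to one symbol for annotation.

What passing recovery tests shows: that the pipeline detects planted
threefold enrichment with power above 0.95 around 300 upregulated genes,
holds its null rejection rate near the nominal 5% (the exact test is
slightly conservative, about 4%, from discreteness), selects the 0.6
threshold whenever within-module correlation is near 0.75, and recovers
planted modules and sample blocks essentially perfectly. What it does not
show: robustness to batch effects, count noise (the generator is Gaussian
on the log scale, not negative binomial), isoform structure, correlated
missingness beyond the block signatures, or miscalibrated DE statistics —
real cohorts can fail in all of those ways.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, generators are pure
functions of (config, seed), and reruns of a flow with identical inputs are
identical apart from timestamps. The bundled tests run the calibration
recovery at 100 seeded replicates of the standard planted-module matrix
(600 genes by 100 samples), the enrichment null at 1000 replicates of a
3750-gene universe, and block recovery at the full 12000-by-505 proteome;
the whole suite completes in about ten minutes on one CPU.

## Known limitations

* The calibration rank-sum test is degenerate when the gene pool is at or
  barely above the set size (all sets identical); the implementation warns.
* MCL is dense-matrix: fine into the low thousands of nodes, not for
  genome-scale graphs.
* The trend test's construction is one defensible reading of an
  underspecified statistic; its q0 is cohort-dependent.
* Minimum imputation deliberately biases low; correlation estimates among
  heavily-missing features are attenuated, not corrected.
* Phylostratum labels are taken as given; no attempt is made to infer gene
  ages or reconcile conflicting annotations.
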