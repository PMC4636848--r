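---
title: "Consensus methylation subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus methylation subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylotype)
```

# The problem

Bulk tumor methylomes measured on Illumina 450K-style arrays report, per CpG
probe, a beta value $\beta = M/(M+U) \in [0,1]$: the fraction of methylated
signal. Melanoma methylomes are shaped by three interacting processes:
hypermethylation of developmentally poised (PRC2-marked) promoter islands,
genome-wide demethylation of heterochromatic open-sea regions, and dilution
of the tumor signal by infiltrating leukocytes and stroma. `methylotype`
implements a complete, tested pipeline that turns a CpG-by-sample beta
matrix plus a normal-cell reference into reproducible methylation subtypes
(MS1, MS2, MS3), a portable nearest-centroid classifier, and the downstream
subtype statistics.

# The pipeline

## Preprocessing

1. **Beta computation.** $\beta = M/(M+U)$, with $M+U=0$ giving a missing
   value rather than 0: the ratio is undefined, and imputation is the
   appropriate remedy.
2. **KNN imputation** (`imputeKNN`, $k=10$). For a probe row with missing
   entries, candidate donor rows are those observed in the missing column;
   distance is the Euclidean distance over the columns observed in both
   rows, scaled by the number of shared columns (so rows with different
   missingness patterns are comparable); the $k$ nearest donors contribute
   an inverse-distance weighted mean, and a zero-distance donor set
   short-circuits to its plain mean. An independent brute-force oracle in
   the test suite checks this contract to $10^{-9}$ on randomized
   instances.
3. **Peak-based type I/II correction** (`peakCorrect`). The two Infinium
   chemistries report systematically different beta distributions; type II
   betas are compressed toward the middle. Per sample and per assay type,
   the beta density is estimated with an Epanechnikov kernel
   (`stats::density`, bandwidth = kernel SD = 0.05) on the grid
   $0, 0.001, \dots, 1$; the unmethylated peak is the density argmax on
   $[0, 0.5)$, the methylated peak the argmax on $[0.5, 1]$. The linear map
   $x \mapsto (x - p_u)/(p_m - p_u)$ moves the peaks to 0 and 1, and
   results are capped into $[0,1]$. Type I and type II probes are never
   pooled for peak estimation.
4. **Sex-chromosome removal**, last, matching the stated processing order
   (impute, correct, drop X/Y).

Peak-correction guards: at least 50 values per slice, and a minimum peak
separation of 0.2. A slice failing either guard is left uncorrected and
flagged in the peaks report. The bandwidth and grid are not dictated by the
procedure itself; 0.05 and step 0.001 resolve modes at least 0.1 apart and
are configurable. Because the map is anchored at the density modes,
correction is idempotent up to grid resolution: on corrected data the
estimated peaks sit within 0.05 of the interval ends (asserted in the
tests).

## Aberrant CpG selection

Against a melanocyte reference, with defaults
$(\mathrm{ref}_{low}, \mathrm{ref}_{high}, t, f) = (0.1, 0.9, 0.5, 0.2)$:

* **tumor-methylated**: mean reference beta $< 0.1$ and $\beta > 0.5$ in at
  least $\lceil f n \rceil$ tumors (10 of 50);
* **tumor-demethylated**: mean reference beta $> 0.9$ and $\beta < 0.5$ in
  at least $\lceil f n \rceil$ tumors.

Inequalities are strict, as printed. With several reference arrays the
*mean* reference beta must pass the gate — robust to one noisy array; a
per-array unanimity rule is the plausible alternative and is deliberately
not used. The two gates are mutually exclusive, so the sets are disjoint
for any input. `combineSets` concatenates methylated-then-demethylated for
clustering.

## Consensus clustering

`bootstrapCoclustering` runs 1000 (default) hierarchical clusterings
(Euclidean distance, Ward linkage) of the samples over bootstrap-resampled
probe sets, cutting the dendrogram into 2 clusters on odd iterations and 3
on even ones, and records for every sample pair the fraction of iterations
in which it co-clustered. Two genuinely open choices are resolved as
follows and parameterized:

* **What is resampled.** Probes (features) are resampled with replacement.
  Every sample pair is then present in every iteration, so the frequency
  denominator is exactly `nBoot`; resampling samples instead would require
  pairwise-presence denominators.
* **The 2-vs-3 cut schedule.** A deterministic alternation rather than an
  extra random draw, pooling both cut depths into one frequency matrix.
  Including the 2-cuts stabilises pairs that straddle the weakest split.

The co-clustering matrix is then reordered by hierarchical clustering with
Pearson-correlation distance ($1 - r$ of its rows) and Ward linkage, and
cut into $k = 3$ consensus groups. Ward dialect matters across
implementations: `hclust` method `ward.D2` (the minimum-variance criterion
on unsquared distances) is used throughout and recorded in the result
object. Samples with a zero-variance co-clustering row get unit distance to
all others, with a message.

Groups are renamed by decreasing mean beta over promoter-island probes
(TSS200/TSS1500 and island): MS1 is the most promoter-methylated group, MS3
the least. This makes labels invariant to the arbitrary group numbering of
the dendrogram cut.

## Nearest-centroid classification

`buildCentroids` takes per-subtype means over the combined aberrant set;
`classifySamples` assigns each external sample to the centroid with the
smallest Euclidean distance over the probes present and non-missing in that
sample. Cross-platform use silently shrinks the probe set, so a minimum
coverage of 50% of centroid probes is enforced; exact ties (within
$10^{-12}$ relative tolerance) go to the lower-numbered subtype with a
warning. `labelAgreement` reports the co-occurrence of two labelings as the
best one-to-one label matching (all $3! = 6$ permutations examined) of the
contingency-table trace over common samples, with a Monte-Carlo Fisher
exact p-value (fixed seed, $10^5$ replicates) — two independent clusterings
carry no shared label semantics, so permutation matching is the honest
definition.

## Downstream statistics

Region-set summaries (`regionSetMeans` with `regionSetDefaults`:
promoter-island, away-from-genes open sea, poised promoter),
Kruskal-Wallis/ANOVA group tests, per-gene panel ANOVA with
Benjamini-Hochberg adjustment (constant genes return $p = 1$ rather than
failing the panel), Fisher association of two subtype labelings,
log-rank/Cox survival comparisons (both the three-group log-rank and the
MS1-vs-rest Cox hazard ratio are reported, since either contrast is a
reasonable reading of a "Cox p-value" for three groups), and the RNA-seq
normalization chain in its printed order: quantile normalization
(`limma::normalizeQuantiles`), offset $+32$, cap at 65,000, $\log_2$,
per-gene median centring.

# The synthetic cohort generator

`generateCohort` draws cohorts with the structure the analysis assumes, and
is the basis of every end-to-end test. Hierarchy, per probe class:

| class | melanocyte ref | leukocyte ref | tumor intrinsic |
|---|---|---|---|
| poised promoter island (10%) | ~0.05 | ~0.05 | 0.70 / 0.45 / 0.25 + probe shift |
| heterochromatin open sea (10%) | ~0.95 | ~0.95 | 0.30 / 0.45 / 0.60 + probe shift |
| cell-type discriminating (5%) | low or high | opposite | = melanocyte |
| neutral (72%) | bimodal + mid | = melanocyte | = melanocyte |
| sex chromosome (3%) | as neutral | as neutral | = melanocyte |

The observed mixture mean is
$\mu = p \cdot \beta_{tumor} + (1-p) \cdot \beta_{leukocyte}$ with
per-sample purity $p$ drawn around subtype means $(0.90, 0.70, 0.50)$;
measurement noise is Beta-distributed with concentration 50 (betas are
bounded fractions, so a Beta noise model keeps draws in range without
truncation artifacts); type II probes (70%) are then compressed
$x \mapsto a + (b-a)x$ with $(a,b) = (0.08, 0.92)$; finally entries go
missing at rate $5\times10^{-4}$. The pre-compression betas are retained as
ground truth for the correction benchmark.

Two generator choices deserve emphasis:

* **The neutral background is bimodal**, with components near 0.015 and
  0.985 (40% each) plus a mid-uniform component (20%). Real 450K beta
  distributions are strongly bimodal — most CpGs are stably unmethylated or
  stably methylated in every cell type — and peak-based correction is only
  well-posed because of those anchoring modes. A flat neutral background
  would leave the per-sample density without reliable peaks and make the
  correction step arbitrary, which is a failure of the simulated data, not
  of the method.
* **The heterochromatin demethylation depth** defaults to tumor-intrinsic
  means $(0.30, 0.45, 0.60)$ for MS1/2/3. The demethylated-CpG rule calls a
  probe only if tumors actually drop below $\beta = 0.5$; after admixture
  with high-beta leukocyte signal, a shallower gradient would leave
  essentially no tumor below the threshold and the planted demethylated
  compartment undiscoverable by construction. The chosen depth puts MS1
  tumors at observed means near 0.37 — demethylated enough to call,
  while preserving the MS1 < MS2 < MS3 open-sea gradient.

The probe-level structure (classes, baseline means, aberration depths,
assay chemistry, annotation) is driven by a separate `platformSeed`, while
sample-level draws (purity, noise, missingness, expression, survival) use
`seed`. Cohorts sharing a platform are the synthetic analogue of two
cohorts profiled on the same array: probe IDs refer to the same CpGs, so
centroids transfer. Matched expression data carry an immune module rising
with $(1-p)$ and a cell-cycle module elevated in MS1/MS2; survival times
are exponential with a hazard ratio of 2.5 for MS1 and uniform censoring on
$(0, 120)$.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: probe-level chemistry beyond a single affine
type-II compression (no dye bias, no background signal, no IDAT-level
artifacts), copy-number effects on beta, batch structure, spatially
correlated probes within CpG islands, more than one admixing normal cell
type (stroma and leukocytes are collapsed into a single leukocyte profile,
consistent with the low-purity subtype resembling blood leukocytes), and
sex-specific methylation (X/Y probes exist only to exercise the removal
filter). Effect sizes are chosen so the three groups are clearly, but not
degenerately, separable; real cohorts will sit closer to the decision
boundaries.

# Numerical choices and degenerate inputs

* Peak search windows $[0, 0.5)$ / $[0.5, 1]$; separation guard 0.2;
  unusable slices pass through unchanged with `corrected = FALSE`.
* The Kruskal-Wallis statistic of an all-constant vector is defined as 0
  (the rank variance is degenerate, and no evidence of group difference
  exists).
* Monte-Carlo exact tests (3x3 and larger) use a caller-supplied seed and
  $10^5$ replicates by default; their p-value floor is $\approx 10^{-5}$.
* Merge ties in `hclust` are resolved by its lowest-index rule, making the
  clustering deterministic for fixed input.
* `imputeKNN` refuses all-missing rows (there is nothing to impute from)
  and falls back to all available donors, with a warning, when fewer than
  $k$ exist.

# Problem sizes used in the shipped checks

The end-to-end checks run on the default synthetic conditions: 50 tumors
(20/15/15) by 20,000 CpGs, six melanocyte reference arrays, 200 bootstrap
iterations, two independent cohorts for the transfer benchmark, 1,000
null replicates for test-size checks, and 11 replicates of a 300-sample
cohort for hazard-ratio recovery. These sizes give stable pass/fail
behaviour for every property while keeping a full run in the order of a
minute; all of them scale up through the exported parameters.

# Known limitations

The consensus procedure fixes $k = 3$ by design and ships no automatic
model-order selection (consensus CDF / PAC criteria are out of scope); the
classifier is unshrunken nearest-centroid, with no assignment
probabilities; tumor-purity estimation is represented only by the planted
truth and an immune-signature proxy, not by a deconvolution method; and the
selection rules operate per CpG with no region-level (DMR) aggregation.
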