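# methylotype

Consensus DNA methylation subtyping of tumor cohorts from Illumina
450K-style beta-value matrices.

Bulk tumor methylomes mix three signals: hypermethylation of
developmentally poised (PRC2-marked) promoter CpG islands, genome-wide
demethylation of heterochromatic open-sea regions, and dilution by
infiltrating leukocytes. `methylotype` is for analysts who want to turn a
CpG-by-sample beta matrix (β = M/(M+U) ∈ [0,1]) plus a normal-cell
reference into reproducible methylation subtypes and a portable classifier.
It implements:

* **Preprocessing** — beta computation, k-nearest-neighbour imputation
  (k = 10), per-sample peak-based correction of the Infinium type I/II
  chemistries (Epanechnikov kernel density; unmethylated peak → 0,
  methylated peak → 1, linear stretch, capped), and X/Y probe removal.
* **Aberrant CpG selection** — tumor-methylated CpGs (β < 0.1 in the
  reference and β > 0.5 in ≥ 20 % of tumors) and tumor-demethylated CpGs
  (the printed mirror: β > 0.9 and β < 0.5 in ≥ 20 %).
* **Consensus clustering** — 1000 bootstrap hierarchical clusterings
  (Euclidean distance, Ward linkage) over resampled probe sets, cut into
  2 or 3 clusters alternately; the sample-pair co-clustering frequency
  matrix is reclustered (Pearson distance, Ward) and cut into the three
  methylation subtypes MS1/MS2/MS3, named by decreasing promoter-island
  methylation.
* **Nearest-centroid classification** — per-subtype mean-beta centroids
  over the combined aberrant set; external samples are assigned to the
  nearest centroid in Euclidean distance, and `labelAgreement` quantifies
  cross-cohort co-occurrence with a Monte-Carlo Fisher exact test.
* **Downstream statistics** — region-set methylation summaries,
  Kruskal-Wallis/ANOVA tests, gene-panel ANOVA with Benjamini-Hochberg
  FDR, subtype association tests, log-rank/Cox survival comparisons, and
  the RNA-seq normalization chain (quantile → +32 → cap 65,000 → log2 →
  median-center).
* **A synthetic cohort generator** — seeded cohorts with three planted
  subtypes, melanocyte/leukocyte reference profiles, purity admixture,
  type-II beta compression, missing values, matched expression modules and
  survival times, with full ground truth for benchmarking.

The data containers are Bioconductor-style S4 classes; the central
`BetaSet` extends `SummarizedExperiment` (assay `"beta"`, probe annotation
in `rowData`).

## Worked example

```r
library(methylotype)

cfg    <- simulationConfig(nPerSubtype = c(10L, 8L, 8L), nCpgs = 6000L, seed = 5L)
cohort <- generateCohort(cfg)
cohort
#> SyntheticCohort: 26 tumors x 6000 CpGs
#> MS1 MS2 MS3
#>  10   8   8
#>   planted aberrant CpGs: 600 methylated / 600 demethylated

tumors    <- preprocessPipeline(cohort@tumor)
reference <- preprocessPipeline(BetaSet(cohort@melanocyteRef,
                                        probeAnnotation(cohort)))
tumors
#> BetaSet: 5820 CpG probes x 26 samples
#>   beta range [0.000, 1.000], 0 missing (0%)
#>   annotation: chromosome, gene_region, island_relation, chromatin_state, cpg_class, assay_type

sets <- selectAberrantCpGs(tumors, reference)
sets
#> AberrantCpGSets: 591 tumor-methylated, 602 tumor-demethylated CpGs
#>   parameters: ref_low=0.1, ref_high=0.9, tumor_threshold=0.5, tumor_fraction=0.2

subtypes <- discoverSubtypes(tumors, combineSets(sets), nBoot = 500L, seed = 17L)
table(called = subtypeLabels(subtypes), planted = subtypeLabels(cohort))
#>       planted
#> called MS1 MS2 MS3
#>    MS1  10   0   0
#>    MS2   0   8   0
#>    MS3   0   0   8
```

The 5,820 surviving probes are the 6,000 simulated CpGs minus X/Y; the
selected sets (591/602) recover the 600 + 600 planted aberrant CpGs almost
exactly, and the consensus cut reproduces the planted subtypes. Centroids
built on this cohort classify an independently generated cohort from the
same probe universe:

```r
cen      <- buildCentroids(tumors, subtypeLabels(subtypes), combineSets(sets))
external <- preprocessPipeline(generateCohort(simulationConfig(
                nPerSubtype = c(10L, 8L, 8L), nCpgs = 6000L, seed = 99L))@tumor)
head(classifySamples(external, cen), 3)
#>   sample_id assigned    d_MS1    d_MS2    d_MS3 n_probes_used   margin   tie
#> 1      T001      MS1 2.528973 9.938251 16.14006          1193 7.409278 FALSE
#> 2      T002      MS1 2.620750 9.725617 15.92701          1193 7.104867 FALSE
#> 3      T003      MS1 2.544141 9.512091 15.69317          1193 6.967951 FALSE
#> co-occurrence with the external cohort's own clustering: 1.00 (Fisher P = 1e-05)
```

`d_MS1..d_MS3` are Euclidean distances to the three centroids over the
1,193 shared aberrant probes; `margin` is the gap between the best and
second-best centroid. Survival follows the planted MS1 hazard
(`survivalCompare` on the cohort's clinical table gives an MS1-vs-rest
hazard ratio of 7.30, Cox P = 0.0012 — a wide small-sample estimate of the
planted ratio 2.5 at n = 26).

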