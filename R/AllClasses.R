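#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.GENE_REGIONS     <- c("TSS200", "TSS1500", "body", "none")
.ISLAND_RELATIONS <- c("island", "shore_shelf", "open_sea")
.ASSAY_TYPES      <- c("I", "II")
.MS_LEVELS        <- c("MS1", "MS2", "MS3")

#' BetaSet: CpG-by-sample methylation fractions
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay,
#' `"beta"`, the matrix of per-CpG methylation fractions (0 = unmethylated,
#' 1 = fully methylated, `NA` = missing).  Probe annotation (chromosome,
#' gene-region class, CpG-island relation, chromatin state, Infinium assay
#' type) lives in `rowData`.
#'
#' @slot .Data inherited SummarizedExperiment internals.
#' @seealso [BetaSet()], [betas()], [probeAnnotation()]
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- NULL
    if (!"beta" %in% names(assays(object)))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (!is.numeric(b))
            msg <- c(msg, "beta assay must be numeric")
        rng <- suppressWarnings(range(b, na.rm = TRUE))
        if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
            msg <- c(msg, "beta values must lie in [0, 1] (or be NA)")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "unique probe IDs (rownames) are required")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "unique sample IDs (colnames) are required")
    if (is.null(msg)) TRUE else msg
})

#' Construct a BetaSet
#'
#' @param betas numeric matrix of beta values with probe IDs as rownames and
#'   sample IDs as colnames. Values outside \[0, 1\] are rejected.
#' @param annotation optional probe annotation: a `data.frame` (or `DataFrame`)
#'   with a `probe_id` column or probe IDs as rownames, covering at least the
#'   probes of `betas`. Recognised columns: `chromosome`, `gene_region`
#'   (`TSS200`, `TSS1500`, `body`, `none`), `island_relation` (`island`,
#'   `shore_shelf`, `open_sea`), `chromatin_state`, `assay_type` (`I`/`II`).
#'
#' @return a [BetaSet-class] object.
#' @examples
#' b <- matrix(runif(12), 4, 3,
#'             dimnames = list(paste0("cg", 1:4), paste0("S", 1:3)))
#' BetaSet(b)
#' @export
BetaSet <- function(betas, annotation = NULL) {
    betas <- as.matrix(betas)
    storage.mode(betas) <- "double"
    if (is.null(rownames(betas)))
        stop("'betas' must have probe IDs as rownames")
    if (is.null(colnames(betas)))
        stop("'betas' must have sample IDs as colnames")
    rd <- if (is.null(annotation)) {
        DataFrame(row.names = rownames(betas))
    } else {
        .alignAnnotation(annotation, rownames(betas))
    }
    se <- SummarizedExperiment(assays = list(beta = betas), rowData = rd)
    new("BetaSet", se)
}

## Reorder an annotation table to a probe vector, checking coverage and the
## categorical vocabularies.
.alignAnnotation <- function(annotation, probes) {
    ann <- as.data.frame(annotation)
    if ("probe_id" %in% colnames(ann)) {
        rownames(ann) <- ann$probe_id
        ann$probe_id <- NULL
    }
    missing <- setdiff(probes, rownames(ann))
    if (length(missing))
        stop("annotation lacks ", length(missing), " probe(s), e.g. ",
             paste(utils::head(missing, 5), collapse = ", "))
    ann <- ann[probes, , drop = FALSE]
    .checkVocab <- function(col, vocab) {
        if (col %in% colnames(ann)) {
            bad <- setdiff(unique(as.character(ann[[col]])), vocab)
            if (length(bad))
                stop("annotation column '", col, "' contains values outside {",
                     paste(vocab, collapse = ", "), "}: ",
                     paste(utils::head(bad, 5), collapse = ", "))
        }
    }
    .checkVocab("gene_region", .GENE_REGIONS)
    .checkVocab("island_relation", .ISLAND_RELATIONS)
    .checkVocab("assay_type", .ASSAY_TYPES)
    DataFrame(ann)
}

#' CoClusteringMatrix: bootstrap co-clustering frequencies
#'
#' Symmetric sample-by-sample matrix of the frequency with which each sample
#' pair fell into the same cluster across bootstrap hierarchical clusterings.
#'
#' @slot values numeric matrix in \[0, 1\], symmetric, unit diagonal.
#' @slot nBoot number of bootstrap iterations.
#' @slot ksUsed the cluster counts used across iterations (multiset over 2:3).
#' @export
setClass("CoClusteringMatrix",
    representation(values = "matrix", nBoot = "integer", ksUsed = "integer"))

setValidity("CoClusteringMatrix", function(object) {
    v <- object@values
    msg <- NULL
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    else {
        if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
        if (any(abs(diag(v) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
    }
    if (any(v < -1e-12 | v > 1 + 1e-12)) msg <- c(msg, "entries must lie in [0, 1]")
    if (object@nBoot < 1L) msg <- c(msg, "nBoot must be positive")
    if (is.null(msg)) TRUE else msg
})

#' ConsensusResult: consensus methylation subtypes
#'
#' @slot labels factor of subtype labels, named by sample ID.
#' @slot coclustering the [CoClusteringMatrix-class] the groups were cut from.
#' @slot ordering dendrogram leaf order of the consensus reordering (for
#'   heatmap display).
#' @slot k number of consensus groups requested.
#' @slot seed RNG seed of the bootstrap stage.
#' @slot dialect the hierarchical-clustering linkage dialect used.
#' @export
setClass("ConsensusResult",
    representation(labels = "factor", coclustering = "CoClusteringMatrix",
                   ordering = "integer", k = "integer", seed = "integer",
                   dialect = "character"))

#' CentroidSet: per-subtype mean methylation profiles
#'
#' The portable nearest-centroid classifier: mean beta values per subtype over
#' the combined aberrant CpG set.
#'
#' @slot centroids numeric matrix, probes x subtypes (columns `MS1`..`MS3`),
#'   probe IDs as rownames, values in \[0, 1\].
#' @export
setClass("CentroidSet", representation(centroids = "matrix"))

setValidity("CentroidSet", function(object) {
    cm <- object@centroids
    msg <- NULL
    if (is.null(rownames(cm))) msg <- c(msg, "centroid probe IDs required as rownames")
    if (ncol(cm) != 3L || !identical(colnames(cm), .MS_LEVELS))
        msg <- c(msg, "centroids must have columns MS1, MS2, MS3")
    if (any(!is.finite(cm)) || any(cm < 0 | cm > 1))
        msg <- c(msg, "centroid values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' AberrantCpGSets: tumor-aberrant CpG selection result
#'
#' @slot methylated probe IDs unmethylated in the reference and methylated in
#'   at least a fraction of tumors.
#' @slot demethylated probe IDs methylated in the reference and unmethylated
#'   in at least a fraction of tumors.
#' @slot parameters named numeric: `ref_low`, `ref_high`, `tumor_threshold`,
#'   `tumor_fraction`.
#' @slot referenceSummary per-probe mean reference beta used for the gates.
#' @export
setClass("AberrantCpGSets",
    representation(methylated = "character", demethylated = "character",
                   parameters = "numeric", referenceSummary = "numeric"))

setValidity("AberrantCpGSets", function(object) {
    if (length(intersect(object@methylated, object@demethylated)))
        "methylated and demethylated sets must be disjoint" else TRUE
})

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' See [simulationConfig()] for the user-facing constructor and the meaning
#' and defaults of every slot.
#'
#' @export
setClass("SimulationConfig",
    representation(
        nPerSubtype          = "integer",
        nCpgs                = "integer",
        classFractions       = "numeric",
        promoterMeans        = "numeric",
        heterochromatinMeans = "numeric",
        purityMeans          = "numeric",
        betaPrecision        = "numeric",
        type2Compression     = "numeric",
        missingRate          = "numeric",
        fractionType2        = "numeric",
        nMelanocyteRefs      = "integer",
        probePrecision       = "numeric",
        neutralModes         = "numeric",
        neutralWeights       = "numeric",
        probeShiftSd         = "numeric",
        purityPrecision      = "numeric",
        nGenes               = "integer",
        nModuleGenes         = "integer",
        hazardRatioMS1       = "numeric",
        baselineHazard       = "numeric",
        censoringMax         = "numeric",
        platformSeed         = "integer",
        seed                 = "integer"))

.CPG_CLASSES <- c("poised_promoter_island", "heterochromatin_opensea",
                  "celltype_discriminating", "neutral", "sex_chromosome")

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (length(object@nPerSubtype) != 3L || any(object@nPerSubtype < 1L))
        msg <- c(msg, "nPerSubtype must be 3 positive integers")
    if (object@nCpgs < 1L) msg <- c(msg, "nCpgs must be positive")
    cf <- object@classFractions
    if (!identical(names(cf), .CPG_CLASSES) || any(cf < 0))
        msg <- c(msg, paste("classFractions must be non-negative and named",
                            paste(.CPG_CLASSES, collapse = ", ")))
    if (abs(sum(cf) - 1) > 1e-9)
        msg <- c(msg, "classFractions must sum to 1 (tolerance 1e-9)")
    if (length(object@promoterMeans) != 3L ||
        any(diff(object@promoterMeans) >= 0))
        msg <- c(msg, "promoterMeans must be strictly decreasing MS1 > MS2 > MS3")
    if (length(object@heterochromatinMeans) != 3L ||
        any(object@heterochromatinMeans < 0 | object@heterochromatinMeans > 1))
        msg <- c(msg, "heterochromatinMeans must be 3 values in [0, 1]")
    if (length(object@purityMeans) != 3L ||
        any(object@purityMeans <= 0 | object@purityMeans > 1) ||
        any(diff(object@purityMeans) >= 0))
        msg <- c(msg, "purityMeans must be in (0, 1], strictly increasing MS3 -> MS1")
    if (object@betaPrecision <= 0) msg <- c(msg, "betaPrecision must be positive")
    tc <- object@type2Compression
    if (length(tc) != 2L || any(tc < 0 | tc > 1) || tc[1] >= tc[2])
        msg <- c(msg, "type2Compression must be (a, b) in [0, 1] with a < b")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must lie in [0, 1)")
    if (object@fractionType2 < 0 || object@fractionType2 > 1)
        msg <- c(msg, "fractionType2 must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' SyntheticCohort: a generated cohort with planted ground truth
#'
#' @slot tumor [BetaSet-class] of observed tumor betas (annotation in rowData).
#' @slot melanocyteRef matrix of observed melanocyte reference betas.
#' @slot leukocyteRef one-column matrix of observed leukocyte betas.
#' @slot truthBeta tumor betas before type-II compression and missingness
#'   (the target the peak correction should recover).
#' @slot truthLabels planted subtype per sample (factor MS1/MS2/MS3).
#' @slot truthMethylated,truthDemethylated planted aberrant probe IDs.
#' @slot truthPurity planted per-sample tumor-cell fraction.
#' @slot expression gene-by-sample matrix on a log2-like scale.
#' @slot modules list of flagged gene sets (`immune_response`, `cell_cycle`).
#' @slot survival data.frame with `sample_id`, `time`, `event`.
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("SyntheticCohort",
    representation(tumor = "BetaSet", melanocyteRef = "matrix",
                   leukocyteRef = "matrix", truthBeta = "matrix",
                   truthLabels = "factor", truthMethylated = "character",
                   truthDemethylated = "character", truthPurity = "numeric",
                   expression = "matrix", modules = "list",
                   survival = "data.frame", config = "SimulationConfig"))

setValidity("SyntheticCohort", function(object) {
    msg <- NULL
    probes <- rownames(object@tumor)
    if (!all(object@truthMethylated %in% probes) ||
        !all(object@truthDemethylated %in% probes))
        msg <- c(msg, "truth probe sets must be contained in the annotation")
    if (!identical(names(object@truthPurity), colnames(object@tumor)))
        msg <- c(msg, "truthPurity must be named by the tumor samples")
    if (is.null(msg)) TRUE else msg
})
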