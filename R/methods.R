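#' @describeIn betas beta matrix of a BetaSet
#' @export
setMethod("betas", "BetaSet", function(x) assay(x, "beta"))

#' @describeIn betas a matrix is returned as-is
#' @export
setMethod("betas", "matrix", function(x) x)

#' @describeIn betas observed tumor betas of a synthetic cohort
#' @export
setMethod("betas", "SyntheticCohort", function(x) assay(x@tumor, "beta"))

#' @describeIn probeAnnotation annotation stored in the rowData
#' @export
setMethod("probeAnnotation", "BetaSet", function(x) {
    as.data.frame(rowData(x))
})

#' @describeIn probeAnnotation annotation of the generated probes
#' @export
setMethod("probeAnnotation", "SyntheticCohort", function(x) {
    probeAnnotation(x@tumor)
})

#' @describeIn subtypeLabels consensus subtype labels
#' @export
setMethod("subtypeLabels", "ConsensusResult", function(x) x@labels)

#' @describeIn subtypeLabels planted truth labels
#' @export
setMethod("subtypeLabels", "SyntheticCohort", function(x) x@truthLabels)

#' @describeIn centroids centroid matrix
#' @export
setMethod("centroids", "CentroidSet", function(x) x@centroids)

#' @describeIn coclustering frequency matrix
#' @export
setMethod("coclustering", "CoClusteringMatrix", function(x) x@values)

#' @describeIn coclustering frequency matrix underlying a consensus result
#' @export
setMethod("coclustering", "ConsensusResult", function(x) x@coclustering@values)

#' @describeIn combineSets methylated-then-demethylated concatenation
#' @export
setMethod("combineSets", "AberrantCpGSets", function(x) {
    unique(c(x@methylated, x@demethylated))
})

setMethod("show", "BetaSet", function(object) {
    cat("BetaSet:", nrow(object), "CpG probes x", ncol(object), "samples\n")
    b <- assay(object, "beta")
    nmiss <- sum(is.na(b))
    cat(sprintf("  beta range [%.3f, %.3f], %d missing (%.3g%%)\n",
                suppressWarnings(min(b, na.rm = TRUE)),
                suppressWarnings(max(b, na.rm = TRUE)),
                nmiss, 100 * nmiss / length(b)))
    if (ncol(rowData(object)))
        cat("  annotation:", paste(colnames(rowData(object)), collapse = ", "),
            "\n")
})

setMethod("show", "CoClusteringMatrix", function(object) {
    cat("CoClusteringMatrix:", nrow(object@values), "samples,",
        object@nBoot, "bootstraps (k in {",
        paste(sort(unique(object@ksUsed)), collapse = ", "), "})\n")
})

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult:", length(object@labels), "samples in",
        nlevels(droplevels(object@labels)), "consensus groups\n")
    print(table(object@labels))
    cat("  linkage dialect:", object@dialect, "\n")
})

setMethod("show", "CentroidSet", function(object) {
    cat("CentroidSet:", nrow(object@centroids), "probes x 3 subtypes\n")
    print(round(apply(object@centroids, 2, mean), 3))
})

setMethod("show", "AberrantCpGSets", function(object) {
    cat("AberrantCpGSets:", length(object@methylated), "tumor-methylated,",
        length(object@demethylated), "tumor-demethylated CpGs\n")
    cat("  parameters:",
        paste(names(object@parameters), signif(object@parameters, 3),
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", sum(object@nPerSubtype), "samples (",
        paste(object@nPerSubtype, collapse = "/"), "),",
        object@nCpgs, "CpGs, seed", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:", ncol(object@tumor), "tumors x",
        nrow(object@tumor), "CpGs\n")
    print(table(object@truthLabels))
    cat("  planted aberrant CpGs:", length(object@truthMethylated),
        "methylated /", length(object@truthDemethylated), "demethylated\n")
})
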