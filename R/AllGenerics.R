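#' Extract the beta-value matrix
#'
#' @param x a [BetaSet-class], [SyntheticCohort-class], or plain matrix.
#' @return numeric CpG-by-sample matrix of methylation fractions.
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' Extract the probe annotation
#'
#' @param x a [BetaSet-class] or [SyntheticCohort-class].
#' @return `data.frame` of per-probe annotation, rownames = probe IDs.
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))

#' Subtype labels of a result object
#'
#' @param x a [ConsensusResult-class] or [SyntheticCohort-class] (planted truth).
#' @return named factor of subtype labels.
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' Centroid matrix of a CentroidSet
#'
#' @param x a [CentroidSet-class].
#' @return probe-by-subtype matrix of mean beta values.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' Co-clustering frequency matrix
#'
#' @param x a [CoClusteringMatrix-class] or [ConsensusResult-class].
#' @return symmetric sample-by-sample matrix of co-clustering frequencies.
#' @export
setGeneric("coclustering", function(x) standardGeneric("coclustering"))

#' Combine the aberrant CpG sets for clustering
#'
#' Concatenates the methylated and demethylated probe sets
#' (methylated first, stable order, no duplicates) into the probe list used
#' by the consensus clustering and the centroid classifier.
#'
#' @param x an [AberrantCpGSets-class].
#' @return character vector of probe IDs.
#' @export
setGeneric("combineSets", function(x) standardGeneric("combineSets"))
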