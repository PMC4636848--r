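#' Read and write probe-by-sample beta matrices
#'
#' Tab-separated text with the probe ID in the first column, sample IDs as
#' the header, and `NA` marking missing values — the conventional exchange
#' format for 450K beta matrices.
#'
#' @param path file to read or write.
#' @param x matrix (or [BetaSet-class]) to write.
#' @param idColumn name written for the probe-ID column.
#' @return `readBetaMatrix` returns a numeric matrix with probe rownames.
#' @export
readBetaMatrix <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(dt[[1]])
    m
}

#' @rdname readBetaMatrix
#' @export
writeBetaMatrix <- function(x, path, idColumn = "probe_id") {
    m <- betas(x)
    dt <- data.table::data.table(id = rownames(m), m)
    data.table::setnames(dt, "id", idColumn)
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
    invisible(path)
}

#' Read and write probe annotation tables
#'
#' @param path file to read or write.
#' @param annotation data.frame with a `probe_id` column.
#' @return `readProbeAnnotation` returns a data.frame keyed by `probe_id`.
#' @export
readProbeAnnotation <- function(path) {
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                      colClasses = "character")
}

#' @rdname readProbeAnnotation
#' @export
writeProbeAnnotation <- function(annotation, path) {
    ann <- as.data.frame(annotation)
    if (!"probe_id" %in% colnames(ann))
        ann <- cbind(probe_id = rownames(ann), ann)
    data.table::fwrite(ann, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read and write centroid tables
#'
#' The portable classifier format: columns `probe_id`, `MS1`, `MS2`, `MS3`.
#'
#' @param path file to read or write.
#' @param x a [CentroidSet-class] to write.
#' @return `readCentroids` returns a [CentroidSet-class].
#' @export
readCentroids <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    m <- as.matrix(dt[, .MS_LEVELS, drop = FALSE])
    rownames(m) <- as.character(dt[[1]])
    new("CentroidSet", centroids = m)
}

#' @rdname readCentroids
#' @export
writeCentroids <- function(x, path) {
    stopifnot(is(x, "CentroidSet"))
    dt <- data.table::data.table(probe_id = rownames(x@centroids),
                                 x@centroids)
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Write a synthetic cohort to a directory of text files
#'
#' Emits `tumor_betas.tsv`, `melanocyte_ref.tsv`, `leukocyte_ref.tsv`,
#' `annotation.tsv`, `expression.tsv`, `clinical.tsv` and `truth.json`
#' (planted labels, aberrant probe sets, purity, modules).  The matrices
#' round-trip through [readCohort()] up to float formatting.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "SyntheticCohort"))
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create directory: ", dir)
    paths <- file.path(dir, c("tumor_betas.tsv", "melanocyte_ref.tsv",
                              "leukocyte_ref.tsv", "annotation.tsv",
                              "expression.tsv", "clinical.tsv", "truth.json"))
    names(paths) <- c("tumor", "melanocyte", "leukocyte", "annotation",
                      "expression", "clinical", "truth")
    writeBetaMatrix(betas(cohort), paths["tumor"])
    writeBetaMatrix(cohort@melanocyteRef, paths["melanocyte"])
    writeBetaMatrix(cohort@leukocyteRef, paths["leukocyte"])
    writeProbeAnnotation(probeAnnotation(cohort), paths["annotation"])
    writeBetaMatrix(cohort@expression, paths["expression"])
    clin <- cohort@survival
    data.table::fwrite(clin, paths["clinical"], sep = "\t", quote = FALSE)
    truth <- list(labels = as.list(stats::setNames(
                      as.character(cohort@truthLabels),
                      names(cohort@truthLabels))),
                  methylated = cohort@truthMethylated,
                  demethylated = cohort@truthDemethylated,
                  purity = as.list(cohort@truthPurity),
                  modules = cohort@modules,
                  seed = cohort@config@seed)
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir directory holding the cohort files.
#' @return list with elements `tumor` (a [BetaSet-class] carrying the
#'   annotation), `melanocyteRef`, `leukocyteRef`, `expression` (matrices),
#'   `clinical` (data.frame) and `truth` (list).
#' @export
readCohort <- function(dir) {
    ann <- readProbeAnnotation(file.path(dir, "annotation.tsv"))
    tumor <- BetaSet(readBetaMatrix(file.path(dir, "tumor_betas.tsv")), ann)
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    list(tumor = tumor,
         melanocyteRef = readBetaMatrix(file.path(dir, "melanocyte_ref.tsv")),
         leukocyteRef = readBetaMatrix(file.path(dir, "leukocyte_ref.tsv")),
         expression = readBetaMatrix(file.path(dir, "expression.tsv")),
         clinical = utils::read.delim(file.path(dir, "clinical.tsv")),
         truth = truth)
}
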