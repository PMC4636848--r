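.checkAligned <- function(tumors, reference) {
    tp <- rownames(tumors); rp <- rownames(reference)
    if (!identical(sort(tp), sort(rp))) {
        d <- c(setdiff(tp, rp), setdiff(rp, tp))
        stop("tumor and reference probes differ; symmetric difference of ",
             length(d), " probe(s), e.g. ",
             paste(utils::head(d, 5), collapse = ", "))
    }
    reference[tp, , drop = FALSE]
}

## Shared core of the two selection rules. `direction` +1 selects
## tumor-methylated probes (reference low, tumors high), -1 the mirror.
.selectAberrant <- function(tumors, reference, direction,
                            refLow = 0.1, refHigh = 0.9,
                            tumorThreshold = 0.5, tumorFraction = 0.2) {
    tm <- betas(tumors)
    rm_ <- .checkAligned(tm, betas(reference))
    refMean <- rowMeans(rm_, na.rm = TRUE)
    needed <- ceiling(tumorFraction * ncol(tm))
    if (direction > 0) {
        gate <- refMean < refLow
        hits <- rowSums(tm > tumorThreshold, na.rm = TRUE)
    } else {
        gate <- refMean > refHigh
        hits <- rowSums(tm < tumorThreshold, na.rm = TRUE)
    }
    rownames(tm)[gate & hits >= needed]
}

#' Select tumor-methylated CpGs against a normal reference
#'
#' A probe is called tumor-methylated when its mean beta across the
#' reference (melanocyte) arrays is below `refLow` and its beta exceeds
#' `tumorThreshold` in at least `tumorFraction` of the tumors
#' (count \eqn{\ge} `ceiling(tumorFraction * n)`); inequalities are strict.
#'
#' @param tumors tumor [BetaSet-class] or matrix.
#' @param reference reference matrix (or [BetaSet-class]) with the same
#'   probes, one or more columns.
#' @param refLow reference-gate threshold (default 0.1).
#' @param tumorThreshold tumor beta threshold (default 0.5).
#' @param tumorFraction required fraction of tumors (default 0.2).
#' @return character vector of probe IDs, in matrix row order.
#' @export
selectMethylated <- function(tumors, reference, refLow = 0.1,
                             tumorThreshold = 0.5, tumorFraction = 0.2) {
    .selectAberrant(tumors, reference, +1, refLow = refLow,
                    tumorThreshold = tumorThreshold,
                    tumorFraction = tumorFraction)
}

#' Select tumor-demethylated CpGs against a normal reference
#'
#' Mirror rule of [selectMethylated()]: mean reference beta above `refHigh`
#' and tumor beta below `tumorThreshold` in at least `tumorFraction` of the
#' tumors.
#'
#' @inheritParams selectMethylated
#' @param refHigh reference-gate threshold (default 0.9).
#' @return character vector of probe IDs, in matrix row order.
#' @export
selectDemethylated <- function(tumors, reference, refHigh = 0.9,
                               tumorThreshold = 0.5, tumorFraction = 0.2) {
    .selectAberrant(tumors, reference, -1, refHigh = refHigh,
                    tumorThreshold = tumorThreshold,
                    tumorFraction = tumorFraction)
}

#' Derive both aberrant CpG sets
#'
#' Runs [selectMethylated()] and [selectDemethylated()] with a shared
#' parameter set and packages the result; the reference gates are mutually
#' exclusive, so the two sets are disjoint by construction.
#'
#' @inheritParams selectMethylated
#' @param refHigh reference gate for the demethylated set.
#' @return an [AberrantCpGSets-class].
#' @export
selectAberrantCpGs <- function(tumors, reference, refLow = 0.1,
                               refHigh = 0.9, tumorThreshold = 0.5,
                               tumorFraction = 0.2) {
    refMean <- rowMeans(betas(reference), na.rm = TRUE)
    new("AberrantCpGSets",
        methylated = selectMethylated(tumors, reference, refLow,
                                      tumorThreshold, tumorFraction),
        demethylated = selectDemethylated(tumors, reference, refHigh,
                                          tumorThreshold, tumorFraction),
        parameters = c(ref_low = refLow, ref_high = refHigh,
                       tumor_threshold = tumorThreshold,
                       tumor_fraction = tumorFraction),
        referenceSummary = refMean)
}

#' Write / read an aberrant CpG set table
#'
#' Two-column TSV: `probe_id`, `set` (`methylated` / `demethylated`).
#'
#' @param x an [AberrantCpGSets-class] to write.
#' @param path file to read or write.
#' @return `readAberrantSets` returns an [AberrantCpGSets-class] (parameters
#'   are not stored in the file and come back as the defaults).
#' @export
writeAberrantSets <- function(x, path) {
    stopifnot(is(x, "AberrantCpGSets"))
    dt <- data.table::data.table(
        probe_id = c(x@methylated, x@demethylated),
        set = rep(c("methylated", "demethylated"),
                  c(length(x@methylated), length(x@demethylated))))
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' @rdname writeAberrantSets
#' @export
readAberrantSets <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    new("AberrantCpGSets",
        methylated = dt$probe_id[dt$set == "methylated"],
        demethylated = dt$probe_id[dt$set == "demethylated"],
        parameters = c(ref_low = 0.1, ref_high = 0.9,
                       tumor_threshold = 0.5, tumor_fraction = 0.2),
        referenceSummary = numeric(0))
}
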