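#' Build per-subtype methylation centroids
#'
#' The centroid of each subtype is the per-probe arithmetic mean beta over
#' its samples, computed on the combined aberrant CpG set.
#'
#' @param x [BetaSet-class] or beta matrix of the training cohort.
#' @param labels factor of subtype labels (`MS1`/`MS2`/`MS3`), named by
#'   sample or aligned with the columns of `x`.
#' @param probes probe IDs to build the centroids over.
#' @return a [CentroidSet-class].
#' @export
buildCentroids <- function(x, labels, probes) {
    m <- betas(x)
    missingProbes <- setdiff(probes, rownames(m))
    if (length(missingProbes))
        stop("probes absent from the matrix: ",
             paste(utils::head(missingProbes, 5), collapse = ", "))
    labels <- .alignLabels(labels, colnames(m))
    cm <- vapply(.MS_LEVELS, function(lv) {
        cols <- which(labels == lv)
        if (!length(cols)) stop("empty subtype group: ", lv)
        rowMeans(m[probes, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(length(probes)))
    rownames(cm) <- probes
    new("CentroidSet", centroids = cm)
}

.alignLabels <- function(labels, sampleIds) {
    f <- factor(as.character(labels), levels = .MS_LEVELS)
    if (!is.null(names(labels))) {
        missing <- setdiff(sampleIds, names(labels))
        if (length(missing))
            stop("labels missing for sample(s): ",
                 paste(utils::head(missing, 5), collapse = ", "))
        names(f) <- names(labels)
        f <- f[sampleIds]
    } else {
        if (length(labels) != length(sampleIds))
            stop("unnamed labels must match the number of samples")
        names(f) <- sampleIds
    }
    f
}

#' Classify samples by nearest centroid
#'
#' Each sample is assigned to the subtype whose centroid is nearest in
#' Euclidean distance, computed over the intersection of the centroid
#' probes with the sample's non-missing probes.  Samples covering less than
#' `minOverlap` of the centroid probes are rejected.  Exact distance ties
#' are broken toward the lower-numbered subtype, with a warning.
#'
#' @param x [BetaSet-class], beta matrix, or a single named vector of betas.
#' @param centroidSet a [CentroidSet-class].
#' @param minOverlap minimum fraction of centroid probes that must be
#'   present and non-missing (default 0.5).
#' @return data.frame with one row per sample: `sample_id`, `assigned`,
#'   distances `d_MS1`..`d_MS3`, `n_probes_used`, `margin` (second-best
#'   minus best distance) and `tie`.
#' @export
classifySamples <- function(x, centroidSet, minOverlap = 0.5) {
    stopifnot(is(centroidSet, "CentroidSet"))
    m <- betas(if (is.null(dim(x))) matrix(x, ncol = 1,
                                           dimnames = list(names(x), "sample"))
               else x)
    cm <- centroidSet@centroids
    res <- lapply(seq_len(ncol(m)), function(j) {
        v <- m[, j]
        shared <- intersect(rownames(cm), rownames(m)[!is.na(v)])
        coverage <- length(shared) / nrow(cm)
        if (coverage < minOverlap)
            stop("sample ", colnames(m)[j], " covers only ",
                 sprintf("%.1f%%", 100 * coverage),
                 " of the centroid probes (minimum ",
                 sprintf("%.0f%%", 100 * minOverlap), ")")
        d <- sqrt(colSums((cm[shared, , drop = FALSE] - v[shared])^2))
        best <- which(d <= min(d) + 1e-12 * max(1, min(d)))
        tie <- length(best) > 1L
        if (tie)
            warning("distance tie for sample ", colnames(m)[j],
                    "; assigned to the lower-numbered subtype")
        sorted <- sort(d)
        data.frame(sample_id = colnames(m)[j],
                   assigned = .MS_LEVELS[min(best)],
                   d_MS1 = d[1], d_MS2 = d[2], d_MS3 = d[3],
                   n_probes_used = length(shared),
                   margin = sorted[2] - sorted[1],
                   tie = tie, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out$assigned <- factor(out$assigned, levels = .MS_LEVELS)
    out
}

#' Agreement between two subtype labelings
#'
#' Builds the contingency table of two labelings over their common samples,
#' computes the co-occurrence fraction as the best achievable
#' `trace / n` over one-to-one relabelings (all label permutations are
#' examined), and tests association with Fisher's exact test (Monte-Carlo
#' for tables larger than 2x2).
#'
#' @param labelsA,labelsB named label vectors or factors.
#' @param seed RNG seed for the Monte-Carlo exact test.
#' @param B Monte-Carlo replicates (default 1e5).
#' @return list with `cooccurrence`, `contingency`, `permutation` (the label
#'   matching applied to `labelsB`), and `p_value`.
#' @export
labelAgreement <- function(labelsA, labelsB, seed = 1L, B = 1e5) {
    a <- .asNamed(labelsA); b <- .asNamed(labelsB)
    common <- intersect(names(a), names(b))
    if (length(common) < 2L) stop("fewer than 2 common samples")
    a <- factor(as.character(a[common]))
    b <- factor(as.character(b[common]))
    tab <- table(a, b)
    la <- levels(a); lb <- levels(b)
    if (length(la) > 3L || length(lb) > 3L)
        stop("labelings over more than 3 groups are not supported")
    ## permute the larger dimension so every one-to-one matching is visited
    tt <- if (nrow(tab) <= ncol(tab)) unclass(tab) else t(unclass(tab))
    perms <- .permutations(seq_len(ncol(tt)))
    traces <- vapply(seq_len(nrow(perms)), function(i) {
        pm <- perms[i, ]
        sum(tt[cbind(seq_len(nrow(tt)), pm[seq_len(nrow(tt))])])
    }, numeric(1))
    bestPerm <- perms[which.max(traces), ]
    permNames <- colnames(tt)
    mc <- nrow(tab) > 2L || ncol(tab) > 2L
    p <- withr::with_seed(as.integer(seed),
        stats::fisher.test(tab, simulate.p.value = mc, B = B)$p.value)
    list(cooccurrence = max(traces) / length(common),
         contingency = tab,
         permutation = stats::setNames(permNames[bestPerm],
                                       rownames(tt)[seq_along(bestPerm)]),
         p_value = p)
}

.asNamed <- function(x) {
    if (is.null(names(x)))
        stop("labels must be named by sample ID")
    x
}

.permutations <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    out <- do.call(rbind, lapply(seq_along(v), function(i) {
        cbind(v[i], .permutations(v[-i]))
    }))
    out
}
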