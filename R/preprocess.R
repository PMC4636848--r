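#' Compute beta values from methylated/unmethylated signal
#'
#' `beta = M / (M + U)` entrywise; probes where both signals are zero have an
#' undefined ratio and become missing.
#'
#' @param M,U non-negative intensity matrices of identical dimension, probe
#'   IDs as rownames and sample IDs as colnames.
#' @param annotation optional probe annotation attached to the result.
#' @return a [BetaSet-class].
#' @examples
#' M <- matrix(c(100, 0, 0), 3, 1, dimnames = list(paste0("cg", 1:3), "S1"))
#' U <- matrix(c(0, 100, 0), 3, 1, dimnames = list(paste0("cg", 1:3), "S1"))
#' betas(computeBeta(M, U))   # 1, 0, NA
#' @export
computeBeta <- function(M, U, annotation = NULL) {
    M <- as.matrix(M); U <- as.matrix(U)
    if (!identical(dim(M), dim(U)) ||
        !identical(dimnames(M), dimnames(U)))
        stop("M and U must share dimensions and dimnames")
    if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
        stop("negative intensities are not allowed")
    tot <- M + U
    b <- M / tot
    b[tot == 0] <- NA_real_
    BetaSet(b, annotation)
}

#' K-nearest-neighbour imputation of missing beta values
#'
#' Row-wise KNN imputation: for each probe row with missing entries, the `k`
#' nearest probe rows (Euclidean distance over the columns observed in both
#' rows, scaled by the number of shared columns) among rows observed in the
#' missing column donate their value, combined as an inverse-distance
#' weighted mean.  A zero-distance neighbour set short-circuits to the plain
#' mean of those neighbours.
#'
#' @param x [BetaSet-class] or matrix with `NA` marking missing entries.
#' @param k number of neighbours (default 10). When fewer candidate
#'   neighbours exist, all available are used with a warning.
#' @return object of the same kind as `x` with no missing entries.
#' @export
imputeKNN <- function(x, k = 10L) {
    m <- betas(x)
    if (k < 1L) stop("k must be >= 1")
    if (!anyNA(m)) return(x)
    allMissing <- rowSums(!is.na(m)) == 0L
    if (any(allMissing))
        stop("probe(s) with no observed values: ",
             paste(utils::head(rownames(m)[allMissing], 5), collapse = ", "))
    out <- m
    xt <- t(m)                     # samples x probes, for fast column sums
    rowsWithNA <- which(rowSums(is.na(m)) > 0L)
    shortage <- FALSE
    for (r in rowsWithNA) {
        xr <- m[r, ]
        obs <- !is.na(xr)
        diff <- xt[obs, , drop = FALSE] - xr[obs]
        d2 <- colSums(diff^2, na.rm = TRUE)
        shared <- colSums(!is.na(diff))
        d <- sqrt(d2 / shared)     # per-shared-column scaling
        d[shared == 0L] <- Inf
        d[r] <- Inf
        for (cc in which(!obs)) {
            cand <- which(!is.na(m[, cc]) & is.finite(d))
            if (!length(cand))
                stop("no candidate neighbours for probe ", rownames(m)[r],
                     ", sample ", colnames(m)[cc])
            if (length(cand) < k) shortage <- TRUE
            nn <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
            dn <- d[nn]
            vals <- m[nn, cc]
            out[r, cc] <- if (any(dn == 0)) {
                mean(vals[dn == 0])
            } else {
                sum(vals / dn) / sum(1 / dn)
            }
        }
    }
    if (shortage)
        warning("fewer than k candidate neighbours for some entries; ",
                "used all available")
    if (is(x, "BetaSet")) {
        assay(x, "beta") <- out
        x
    } else out
}

#' Estimate the unmethylated and methylated density peaks of a sample
#'
#' Epanechnikov kernel density of the beta values, evaluated on the grid
#' 0, 0.001, ..., 1; the unmethylated peak is the density argmax on
#' \[0, 0.5) and the methylated peak the argmax on \[0.5, 1\].  The estimate
#' is flagged unusable when fewer than `minN` values are available or the
#' peaks are separated by less than `minSeparation` (a guard against
#' stretching unimodal samples).
#'
#' @param values numeric vector of beta values (NAs dropped).
#' @param bandwidth kernel standard deviation on the beta scale.
#' @param minN minimum number of observations.
#' @param minSeparation minimum `pMeth - pUnmeth` for a usable estimate.
#' @return list with `pUnmeth`, `pMeth`, `ok`.
#' @examples
#' v <- c(rnorm(5000, 0.2, 0.01), rnorm(5000, 0.8, 0.01))
#' estimatePeaks(v)
#' @export
estimatePeaks <- function(values, bandwidth = 0.05, minN = 50L,
                          minSeparation = 0.2) {
    v <- values[!is.na(values)]
    if (length(v) < minN)
        return(list(pUnmeth = NA_real_, pMeth = NA_real_, ok = FALSE))
    dens <- stats::density(v, bw = bandwidth, kernel = "epanechnikov",
                           from = 0, to = 1, n = 1001L)
    lower <- dens$x < 0.5
    pU <- dens$x[lower][which.max(dens$y[lower])]
    pM <- dens$x[!lower][which.max(dens$y[!lower])]
    list(pUnmeth = pU, pMeth = pM, ok = (pM - pU) >= minSeparation)
}

#' Peak-based correction of the type I/II assay chemistries
#'
#' Per sample and per Infinium assay type independently, the beta density
#' peaks are estimated with [estimatePeaks()]; when usable, the unmethylated
#' peak is moved to 0 and the methylated peak to 1 by the linear map
#' `x -> (x - pUnmeth) / (pMeth - pUnmeth)`, with results capped at 0 and 1.
#' Slices with an unusable peak estimate are left unchanged and flagged.
#' Missing entries stay missing.
#'
#' @param x [BetaSet-class] (annotation with `assay_type` in rowData) or
#'   matrix.
#' @param annotation probe annotation with `assay_type`; taken from `x`
#'   when `x` is an annotated [BetaSet-class].
#' @param bandwidth,minN,minSeparation passed to [estimatePeaks()].
#' @return list with `betas` (same kind as `x`, corrected) and `peaks`, a
#'   data.frame of per-sample/assay peak estimates and `corrected` flags.
#' @export
peakCorrect <- function(x, annotation = NULL, bandwidth = 0.05, minN = 50L,
                        minSeparation = 0.2) {
    m <- betas(x)
    ann <- .resolveAnnotation(x, annotation, require = "assay_type")
    assayType <- as.character(ann[rownames(m), "assay_type"])
    out <- m
    recs <- list()
    for (tp in intersect(.ASSAY_TYPES, unique(assayType))) {
        rows <- assayType == tp
        for (j in seq_len(ncol(m))) {
            est <- estimatePeaks(m[rows, j], bandwidth, minN, minSeparation)
            if (isTRUE(est$ok)) {
                v <- (m[rows, j] - est$pUnmeth) / (est$pMeth - est$pUnmeth)
                out[rows, j] <- pmin(1, pmax(0, v))
            }
            recs[[length(recs) + 1L]] <- data.frame(
                sample_id = colnames(m)[j], assay_type = tp,
                p_unmeth = est$pUnmeth, p_meth = est$pMeth,
                corrected = isTRUE(est$ok), stringsAsFactors = FALSE)
        }
    }
    peaks <- do.call(rbind, recs)
    if (is(x, "BetaSet")) {
        assay(x, "beta") <- out
        list(betas = x, peaks = peaks)
    } else list(betas = out, peaks = peaks)
}

#' Drop probes on the sex chromosomes
#'
#' @param x [BetaSet-class] (with `chromosome` in rowData) or matrix.
#' @param annotation probe annotation with `chromosome`; taken from `x`
#'   when possible. Chromosome labels `X`, `Y` (optionally `chr`-prefixed)
#'   are removed; row order of the survivors is preserved.
#' @return object of the same kind as `x` without X/Y probes.
#' @export
removeSexChromosomes <- function(x, annotation = NULL) {
    m <- betas(x)
    ann <- .resolveAnnotation(x, annotation, require = "chromosome")
    chrom <- sub("^chr", "", as.character(ann[rownames(m), "chromosome"]))
    keep <- !(chrom %in% c("X", "Y"))
    if (is(x, "BetaSet")) x[keep, ] else m[keep, , drop = FALSE]
}

.resolveAnnotation <- function(x, annotation, require) {
    ann <- if (!is.null(annotation)) {
        a <- as.data.frame(annotation)
        if ("probe_id" %in% colnames(a)) {
            rownames(a) <- a$probe_id
        }
        a
    } else if (is(x, "BetaSet")) {
        probeAnnotation(x)
    } else {
        stop("probe annotation is required")
    }
    m <- betas(x)
    missing <- setdiff(rownames(m), rownames(ann))
    if (length(missing))
        stop("annotation lacks ", length(missing), " probe(s), e.g. ",
             paste(utils::head(missing, 5), collapse = ", "))
    lacking <- setdiff(require, colnames(ann))
    if (length(lacking))
        stop("annotation column(s) required: ", paste(lacking, collapse = ", "))
    ann
}

#' Full preprocessing pipeline for a beta (or signal) matrix
#'
#' Applies, in order: beta computation (when `M`/`U` signals are given),
#' KNN imputation of missing values, per-sample peak-based type I/II
#' correction, and removal of X/Y probes.
#'
#' @param x a [BetaSet-class], a beta matrix, or a list with elements `M`
#'   and `U` of signal intensities.
#' @param annotation probe annotation (needed when `x` is not an annotated
#'   [BetaSet-class]); must provide `assay_type` and `chromosome`.
#' @param k neighbours for the imputation.
#' @param bandwidth,minN,minSeparation peak-estimation settings.
#' @return a [BetaSet-class] of corrected autosomal betas; the per-sample
#'   peak estimates are stored in `metadata(result)$peaks`.
#' @export
preprocessPipeline <- function(x, annotation = NULL, k = 10L,
                               bandwidth = 0.05, minN = 50L,
                               minSeparation = 0.2) {
    if (is.list(x) && !is(x, "BetaSet") && all(c("M", "U") %in% names(x))) {
        x <- computeBeta(x$M, x$U, annotation)
    } else if (!is(x, "BetaSet")) {
        x <- BetaSet(betas(x), annotation)
    } else if (!is.null(annotation)) {
        x <- BetaSet(betas(x), annotation)
    }
    if (!all(c("assay_type", "chromosome") %in% colnames(probeAnnotation(x))))
        stop("annotation must provide 'assay_type' and 'chromosome'")
    x <- imputeKNN(x, k = k)
    pc <- peakCorrect(x, bandwidth = bandwidth, minN = minN,
                      minSeparation = minSeparation)
    res <- removeSexChromosomes(pc$betas)
    metadata(res)$peaks <- pc$peaks
    res
}
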